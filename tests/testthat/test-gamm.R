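test_that("a planted cyclic diel effect is recovered", {
  d <- gamm_test_data(n_animals = 4, n_per_animal = 150, seed = 3)
  spec <- model_spec("depth", "gamma_log",
                     cyclic = list(time_of_day = 24),
                     smooth = "current_magnitude", random = "intercept")
  fit <- fit_metric_model(d, spec)
  grid <- seq(0, 23, length.out = 24)
  eff <- predict_effects(fit, "time_of_day", grid = grid,
                         response_scale = FALSE)
  truth <- 0.3 * cos(2 * pi * (grid - 12) / 24)
  expect_gt(cor(eff$estimate, truth), 0.9)
  ## monotone planted current effect recovered over the central 80%
  ce <- predict_effects(fit, "current_magnitude",
                        grid = seq(0.06, 0.54, length.out = 25),
                        response_scale = FALSE)
  expect_true(all(diff(ce$estimate) > -1e-6))
})

test_that("cyclic smooths are continuous across the period boundary", {
  d <- gamm_test_data(n_animals = 3, n_per_animal = 120, seed = 5)
  spec <- model_spec("depth", "gamma_log",
                     cyclic = list(time_of_day = 24,
                                   moon_phase = 2 * pi),
                     random = "intercept")
  fit <- fit_metric_model(d, spec)
  eff <- predict_effects(fit, "time_of_day", grid = c(0, 24),
                         response_scale = FALSE)
  expect_equal(eff$estimate[1], eff$estimate[2], tolerance = 1e-6)
  ## first derivative matches at the boundary
  h <- 1e-3
  e2 <- predict_effects(fit, "time_of_day", grid = c(h, 24 - h),
                        response_scale = FALSE)
  d_left <- as.numeric((eff$estimate[2] - e2$estimate[2]) / h)
  d_right <- as.numeric((e2$estimate[1] - eff$estimate[1]) / h)
  expect_equal(d_left, d_right, tolerance = 1e-2)
  mp <- predict_effects(fit, "moon_phase", grid = c(0, 2 * pi),
                        response_scale = FALSE)
  expect_equal(mp$estimate[1], mp$estimate[2], tolerance = 1e-6)
})

test_that("shrinkage drives a pure-noise covariate toward zero edf", {
  ## shrinkage is stochastic: check the rate over a few replicates
  spec <- model_spec("depth", "gamma_log",
                     cyclic = list(time_of_day = 24),
                     smooth = c("current_magnitude", "noise_cov"),
                     random = "intercept")
  edfs <- vapply(3:7, function(s) {
    d <- gamm_test_data(n_animals = 8, n_per_animal = 250, seed = s)
    fit_metric_model(d, spec)$edf[["s(noise_cov)"]]
  }, numeric(1))
  expect_gte(sum(edfs < 0.5), 4)
  ## the real covariate keeps its degrees of freedom
  d <- gamm_test_data(n_animals = 8, n_per_animal = 250, seed = 3)
  fit <- fit_metric_model(d, spec)
  expect_gt(fit$edf[["s(current_magnitude)"]], 0.5)
  expect_gt(fit$edf[["s(time_of_day)"]], 1)
  ## the null covariate's conditional curve is flat relative to its CI
  eff <- predict_effects(fit, "noise_cov", response_scale = FALSE)
  spread <- max(eff$estimate) - min(eff$estimate)
  width <- mean(eff$upper - eff$lower)
  expect_lt(spread, width)
})

test_that("log-hours offset doubles expected counts exactly", {
  set.seed(21)
  hu <- data.frame(animal_id = rep(c("A", "B"), each = 300),
                   time_of_day = runif(600, 0, 24),
                   moon_phase = runif(600, 0, 2 * pi),
                   covered_hours = runif(600, 0.75, 1))
  mu <- exp(log(0.45) + 0.5 * cos(2 * pi * (hu$time_of_day - 12) / 24)) *
    hu$covered_hours
  hu$n_dives <- rnbinom(600, size = 5, mu = mu)
  spec <- model_spec("n_dives", "negbin_log",
                     cyclic = list(time_of_day = 24,
                                   moon_phase = 2 * pi),
                     random = "intercept", offset = "covered_hours")
  fit <- fit_metric_model(hu, spec)
  nd <- hu[1:5, ]
  nd1 <- nd; nd1$covered_hours <- 1
  nd2 <- nd; nd2$covered_hours <- 2
  p1 <- mgcv::predict.gam(fit$gam, nd1, type = "response")
  p2 <- mgcv::predict.gam(fit$gam, nd2, type = "response")
  expect_equal(as.numeric(p2 / p1), rep(2, 5), tolerance = 1e-12)
})

test_that("random-structure comparison reports AIC and deviance deltas", {
  ## per-animal diel phase shifts favor the factor-smooth structure
  d <- gamm_test_data(n_animals = 6, n_per_animal = 150,
                      phase_shift_sd = 5, seed = 31)
  spec <- model_spec("depth", "gamma_log",
                     cyclic = list(time_of_day = 24),
                     smooth = "current_magnitude")
  cmp <- compare_random_structures(d, spec)
  expect_false(cmp$partial)
  expect_true(cmp$chosen %in% c("intercept", "factor_smooth"))
  expect_equal(cmp$chosen, "factor_smooth")
  expect_gt(cmp$delta_aic, 0)
  ## deviance explained reported for both structures
  expect_true(is.finite(cmp$delta_deviance))
  ## identical diel effects: no assertion on the winner, report only
  d0 <- gamm_test_data(n_animals = 6, n_per_animal = 80,
                       phase_shift_sd = 0, seed = 32)
  cmp0 <- compare_random_structures(d0, spec)
  expect_true(is.finite(cmp0$delta_aic))
})

test_that("fitted curves are stable under covariate rescaling", {
  d <- gamm_test_data(n_animals = 4, n_per_animal = 150, seed = 41)
  spec <- model_spec("depth", "gamma_log",
                     cyclic = list(time_of_day = 24),
                     smooth = "current_magnitude", random = "intercept")
  fit1 <- fit_metric_model(d, spec)
  d2 <- d; d2$current_magnitude <- d2$current_magnitude * 100
  fit2 <- fit_metric_model(d2, spec)
  g <- seq(0.06, 0.54, length.out = 25)
  e1 <- predict_effects(fit1, "current_magnitude", grid = g,
                        response_scale = FALSE)
  e2 <- predict_effects(fit2, "current_magnitude", grid = g * 100,
                        response_scale = FALSE)
  expect_gt(cor(e1$estimate, e2$estimate), 0.999)
  expect_lt(max(abs(e1$estimate - e2$estimate)), 0.01)
})

test_that("degenerate model inputs are rejected informatively", {
  d <- gamm_test_data(n_animals = 1, n_per_animal = 100, seed = 51)
  spec <- model_spec("depth", "gamma_log",
                     cyclic = list(time_of_day = 24), random = "intercept")
  expect_error(fit_metric_model(d, spec), "2 animals")
  expect_error(fit_metric_model(d[0, ], spec), "")
  d2 <- gamm_test_data(n_animals = 3, seed = 52)
  expect_error(
    fit_metric_model(within(d2, rm(depth)), spec), "missing model columns")
})
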