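test_that("simulated OU velocity has the analytic autocorrelation", {
  p <- simulate_ctcrw_track(beta = 1, sigma = 3000, duration_h = 10000 / 60,
                            dt_h = 1 / 60, seed = 99)
  ac <- cor(p$vx[-1], p$vx[-nrow(p)])
  expect_equal(ac, exp(-1 / 60), tolerance = 0.05 / exp(-1 / 60))
  ## beta -> infinity limit: white velocity
  p2 <- simulate_ctcrw_track(beta = 100, sigma = 3000, duration_h = 80,
                             dt_h = 0.1, seed = 5)
  expect_lt(abs(cor(p2$vx[-1], p2$vx[-nrow(p2)])), 0.08)
  ## determinism
  expect_identical(simulate_ctcrw_track(1, 3000, 24, seed = 7),
                   simulate_ctcrw_track(1, 3000, 24, seed = 7))
  expect_error(simulate_ctcrw_track(-1, 1, 10), "beta")
})

test_that("simulated speed is Rayleigh with scale sigma/sqrt(2 beta)", {
  p <- simulate_ctcrw_track(beta = 0.5, sigma = 2000,
                            duration_h = 10000 * 0.05, dt_h = 0.05,
                            seed = 123)
  speed <- sqrt(p$vx^2 + p$vy^2)
  sc <- 2000 / sqrt(2 * 0.5)
  ## thin to quasi-independent samples (10 autocorrelation times apart)
  idx <- seq(1, nrow(p), by = 400)
  ks <- suppressWarnings(
    ks.test(speed[idx], function(q) 1 - exp(-q^2 / (2 * sc^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("degraded observations have calibrated ellipse errors", {
  p <- simulate_ctcrw_track(1, 3000, 24 * 30, dt_h = 1 / 60, seed = 3)
  ## zero noise: observations equal interpolated truth
  o0 <- degrade_to_observations(p, obs_rate = 20, ellipse_scale_m = 0,
                                seed = 2)
  expect_equal(o0$x, o0$true_x)
  expect_equal(o0$semi_major_m, rep(0, nrow(o0)))
  ## with noise: zero-mean errors, chi-square(2) Mahalanobis distances
  o <- degrade_to_observations(p, obs_rate = 400, ellipse_scale_m = 500,
                               seed = 8)
  n <- nrow(o)
  expect_gt(n, 5000)
  ex <- o$x - o$true_x; ey <- o$y - o$true_y
  se <- sqrt(mean(ex^2) / n)
  expect_lt(abs(mean(ex)), 3 * se)
  covs <- divetag:::ellipse_to_cov(o$semi_major_m, o$semi_minor_m,
                                   o$orientation_deg, floor_m = 0)
  m2 <- vapply(seq_len(n), function(i) {
    e <- c(ex[i], ey[i])
    as.numeric(e %*% solve(covs[[i]], e))
  }, numeric(1))
  expect_equal(unname(quantile(m2, 0.95)), qchisq(0.95, 2),
               tolerance = 0.3 / qchisq(0.95, 2))
  expect_true(all(o$semi_major_m >= o$semi_minor_m))
  expect_error(degrade_to_observations(p, obs_rate = 0, 100), "obs_rate")
})

test_that("Kalman likelihood equals the brute-force joint Gaussian", {
  set.seed(21)
  for (case in 1:3) {
    n <- sample(5:10, 1)
    times <- cumsum(runif(n, 0.2, 3))
    obs <- cbind(cumsum(rnorm(n, 0, 2000)), cumsum(rnorm(n, 0, 2000)))
    R_list <- divetag:::ellipse_to_cov(runif(n, 200, 2000),
                                       runif(n, 100, 800),
                                       runif(n, 0, 180))
    for (par in list(c(1, 3000), c(0.3, 800), c(4, 10000))) {
      kf <- divetag:::ctcrw_filter(obs, times, R_list, par[1], par[2],
                                   init_xy = obs[1, ])$loglik
      bf <- ctcrw_loglik_bruteforce(obs, times, R_list, par[1], par[2])
      expect_lt(abs(kf - bf), 1e-6)
    }
  }
})

test_that("claiming larger error ellipses lowers the likelihood", {
  p <- simulate_ctcrw_track(1, 3000, 24 * 5, seed = 31)
  o <- degrade_to_observations(p, 30, 500, seed = 32)
  R1 <- divetag:::ellipse_to_cov(o$semi_major_m, o$semi_minor_m,
                                 o$orientation_deg)
  R2 <- divetag:::ellipse_to_cov(2 * o$semi_major_m, 2 * o$semi_minor_m,
                                 o$orientation_deg)
  obs <- cbind(o$x, o$y)
  t_h <- o$time_h
  ll1 <- divetag:::ctcrw_filter(obs, t_h, R1, 1, 3000, obs[1, ])$loglik
  ll2 <- divetag:::ctcrw_filter(obs, t_h, R2, 1, 3000, obs[1, ])$loglik
  expect_lt(ll2, ll1)
})

test_that("noise-free dense observations pin the smoothed path", {
  p <- simulate_ctcrw_track(1, 2000, 48, dt_h = 1 / 60, seed = 44)
  o <- degrade_to_observations(p, obs_rate = 24 * 30, ellipse_scale_m = 0,
                               seed = 45)
  o$semi_major_m <- o$semi_minor_m <- rep(1, nrow(o)) # ~exact
  obs_ll <- obs_to_lonlat(o)
  fit <- fit_ctcrw(obs_ll, ellipse_floor_m = 1)
  pr <- predict_positions(fit, obs_ll$time)
  err <- geosphere::distGeo(cbind(pr$lon, pr$lat),
                            cbind(obs_ll$lon, obs_ll$lat))
  expect_lt(max(err), 1)
})

test_that("prefilter removes planted outliers and is idempotent", {
  p <- simulate_ctcrw_track(1, 3000, 48, seed = 61)
  o <- degrade_to_observations(p, 24, 100, seed = 62)
  obs <- obs_to_lonlat(o)
  clean <- prefilter_locations(obs)
  expect_equal(nrow(clean), nrow(obs))
  ## plant a point 100 km off-track between close neighbors
  spike <- obs[10, ]
  spike$time <- obs$time[10] + 300
  spike$lat <- spike$lat + 0.9
  with_spike <- rbind(obs[1:10, ], spike, obs[11:nrow(obs), ])
  filtered <- prefilter_locations(with_spike)
  expect_equal(nrow(filtered), nrow(obs))
  expect_false(any(abs(filtered$lat - spike$lat) < 1e-9))
  expect_equal(prefilter_locations(filtered), filtered)
})

test_that("smoother variance never exceeds filter variance", {
  p <- simulate_ctcrw_track(1, 3000, 24 * 4, seed = 71)
  o <- degrade_to_observations(p, 20, 800, seed = 72)
  R <- divetag:::ellipse_to_cov(o$semi_major_m, o$semi_minor_m,
                                o$orientation_deg)
  flt <- divetag:::ctcrw_filter(cbind(o$x, o$y), o$time_h, R, 1, 3000,
                                c(o$x[1], o$y[1]), keep_states = TRUE)
  sm <- divetag:::ctcrw_smooth(flt)
  for (t in seq_len(nrow(flt$m_filt))) {
    expect_true(all(diag(sm$P_smooth[[t]]) <=
                      diag(flt$P_filt[[t]]) + 1e-6))
  }
})

test_that("prediction uncertainty grows inside observation gaps", {
  p <- simulate_ctcrw_track(1, 3000, 24 * 6, seed = 81)
  o <- degrade_to_observations(p, 40, 500, seed = 82)
  ## carve out a 12-h gap in the middle
  mid <- max(o$time_h) / 2
  o <- o[o$time_h < mid - 6 | o$time_h > mid + 6, ]
  obs <- obs_to_lonlat(o)
  fit <- fit_ctcrw(obs)
  t0 <- obs$time[1] - o$time_h[1] * 3600
  gap_time <- t0 + mid * 3600
  at_obs <- obs$time[20]
  pr <- predict_positions(fit, c(gap_time, at_obs))
  expect_gt(pr$ellipse95_semi_major[1], pr$ellipse95_semi_major[2])
  ## anchor: prediction at a tiny-error observation stays close to it
  tiny <- obs
  tiny$semi_major_m <- tiny$semi_minor_m <- rep(5, nrow(tiny))
  fit2 <- fit_ctcrw(tiny, ellipse_floor_m = 5)
  pr2 <- predict_positions(fit2, tiny$time[10])
  d <- geosphere::distGeo(c(pr2$lon, pr2$lat),
                          c(tiny$lon[10], tiny$lat[10]))
  expect_lt(d, 15)
})

test_that("extrapolation beyond the tracked span warns and flags", {
  p <- simulate_ctcrw_track(1, 3000, 48, seed = 91)
  o <- degrade_to_observations(p, 30, 500, seed = 92)
  obs <- obs_to_lonlat(o)
  fit <- fit_ctcrw(obs)
  far <- max(obs$time) + 12 * 3600
  expect_warning(pr <- predict_positions(fit, far), "extrapolate")
  expect_true(pr$extrapolated)
})

test_that("imputations are reproducible and track the smoother", {
  p <- simulate_ctcrw_track(1, 3000, 24 * 4, seed = 101)
  o <- degrade_to_observations(p, 30, 600, seed = 102)
  ## 8-h gap
  mid <- max(o$time_h) / 2
  o <- o[o$time_h < mid - 4 | o$time_h > mid + 4, ]
  obs <- obs_to_lonlat(o)
  fit <- fit_ctcrw(obs)
  t0 <- obs$time[1] - o$time_h[1] * 3600
  times <- t0 + c(mid, o$time_h[15]) * 3600
  imp <- impute_tracks(fit, times, K = 40, seed = 5)
  imp2 <- impute_tracks(fit, times, K = 40, seed = 5)
  expect_identical(imp$x, imp2$x)
  ## across-imputation SD larger in the gap than at an observation time
  expect_gt(sd(imp$x[1, ]), sd(imp$x[2, ]))
  expect_error(impute_tracks(fit, times, K = 1), "at least 2")
})

test_that("rerouting moves shallow points to the isobath", {
  ras <- build_rasters(c(-159, -155, 19, 23), 0.05, n_days = 1, seed = 2)
  offshore <- reroute_land(-158.5, 19.5, ras$bathy)
  expect_false(offshore$moved)
  center <- reroute_land(-157, 21, ras$bathy) # island center
  expect_true(center$moved)
  expect_gt(center$displacement_m, 0)
  moved_depth <- extract_at(ras$bathy, center$lon, center$lat)$value
  expect_gte(moved_depth, 20)
})
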