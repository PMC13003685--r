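## Shared fixtures, all built in code at test time.

t_utc <- function(x) as.POSIXct(x, tz = "UTC")

## A small, hand-checkable behavior log: alternating surface/dive
## records with dives straddling the 50 m / 120 s thresholds.
toy_behavior_log <- function() {
  t0 <- t_utc("2024-03-01 00:00:00")
  rows <- list(
    list("surface", 0, 3600, NA, NA, "none"),
    list("dive", 3600, 3900, 95, 105, "square"),   # 100 m, 300 s -> dive
    list("surface", 3900, 7200, NA, NA, "none"),
    list("dive", 7200, 7500, 44, 54, "u"),         # 49 m -> surface
    list("surface", 7500, 10800, NA, NA, "none"),
    list("dive", 10800, 10900, 396, 404, "v"),     # 100 s -> surface
    list("surface", 10900, 14400, NA, NA, "none"),
    list("dive", 14400, 14700, 59.4, 60.6, "u"),   # 60 m, 300 s -> dive
    list("dive", 14700, 14880, 44.55, 45.45, "v"), # 45 m -> surface
    list("surface", 14880, 18000, NA, NA, "none"),
    list("dive", 18000, 18120, 49.5, 50.5, "u"),   # exactly 50 m, 120 s -> dive
    list("surface", 18120, 21600, NA, NA, "none")
  )
  rec <- do.call(rbind, lapply(rows, function(r) {
    dur <- r[[3]] - r[[2]]
    data.frame(animal_id = "TOY1", kind = r[[1]],
               start = t0 + r[[2]], end = t0 + r[[3]],
               depth_min = r[[4]], depth_max = r[[5]],
               dur_min = dur * 0.99, dur_max = dur * 1.01,
               shape = r[[6]],
               depth = (r[[4]] + r[[5]]) / 2, duration = dur,
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  rec
}

## Write a behavior log in the Wildlife-Computers-style CSV dialect.
write_toy_csv <- function(rec, path) {
  df <- data.frame(DeployID = rec$animal_id,
                   What = tools::toTitleCase(rec$kind),
                   Start = format(rec$start, "%Y-%m-%d %H:%M:%S"),
                   End = format(rec$end, "%Y-%m-%d %H:%M:%S"),
                   DurationMin = rec$dur_min, DurationMax = rec$dur_max,
                   DepthMin = rec$depth_min, DepthMax = rec$depth_max,
                   Shape = ifelse(rec$shape == "none", "", rec$shape))
  write.csv(df, path, row.names = FALSE)
  path
}

## Synthetic 1-Hz triangular dive profile: surface pad, descent to
## `depth` at `rate` m/s, immediate ascent, surface pad.
triangle_profile <- function(depth = 100, rate = 1, pad = 120) {
  up <- seq(0, depth, by = rate)
  prof <- c(rep(0, pad), up, rev(up)[-1], rep(0, pad))
  tdr_profile(t_utc("2024-01-01 00:00:00") + seq_along(prof) - 1, prof)
}

## Trapezoid: descend (depth/rate s), hold `hold` s, ascend.
trapezoid_profile <- function(depth = 80, rate = 2, hold = 300, pad = 120) {
  up <- seq(0, depth, by = rate)
  prof <- c(rep(0, pad), up, rep(depth, hold), rev(up)[-1], rep(0, pad))
  tdr_profile(t_utc("2024-01-01 00:00:00") + seq_along(prof) - 1, prof)
}

## Small flat-bathymetry raster builder.
flat_bathy <- function(depth = 500, lon = seq(-158, -157, by = 0.01),
                       lat = seq(20, 21, by = 0.01)) {
  grid_raster(lon, lat, matrix(depth, length(lon), length(lat)),
              name = "seafloor_depth")
}

## Brute-force joint-Gaussian log-likelihood for the CTCRW state-space
## model on a small instance: builds the full covariance of the stacked
## observation vector by propagating the state moments, then evaluates
## the multivariate normal density directly. Mirrors the model
## definition (prior at the first time: position = first observation,
## variance init_pos_var; velocity stationary), independently of the
## Kalman recursion.
ctcrw_loglik_bruteforce <- function(obs, times, R_list, beta, sigma,
                                    init_pos_var = 1e10) {
  n <- nrow(obs)
  vel_var <- sigma^2 / (2 * beta)
  m <- c(obs[1, 1], 0, obs[1, 2], 0)
  P0 <- diag(c(init_pos_var, vel_var, init_pos_var, vel_var))
  ## state moments and pairwise covariances
  Fs <- list(diag(4))
  for (t in 2:n) {
    Fs[[t]] <- divetag:::ou_discretize4(beta, sigma, times[t] - times[t - 1])$F
  }
  means <- matrix(NA, n, 4)
  covs <- vector("list", n)
  means[1, ] <- m; covs[[1]] <- P0
  for (t in 2:n) {
    Q <- divetag:::ou_discretize4(beta, sigma, times[t] - times[t - 1])$Q
    means[t, ] <- as.numeric(Fs[[t]] %*% means[t - 1, ])
    covs[[t]] <- Fs[[t]] %*% covs[[t - 1]] %*% t(Fs[[t]]) + Q
  }
  ## Cov(s_j, s_k), j <= k: covs[[j]] %*% t(F_k ... F_{j+1})
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 3] <- 1
  big_mu <- as.numeric(t(means %*% t(H)))
  big_S <- matrix(0, 2 * n, 2 * n)
  for (j in 1:n) {
    prod_F <- diag(4)
    for (k in j:n) {
      if (k > j) prod_F <- Fs[[k]] %*% prod_F
      Cjk <- covs[[j]] %*% t(prod_F)
      blk <- H %*% t(Cjk) %*% t(H)  # Cov(s_k, s_j) mapped to obs space
      big_S[(2 * k - 1):(2 * k), (2 * j - 1):(2 * j)] <- blk
      big_S[(2 * j - 1):(2 * j), (2 * k - 1):(2 * k)] <- t(blk)
    }
  }
  for (t in 1:n) {
    id <- (2 * t - 1):(2 * t)
    big_S[id, id] <- big_S[id, id] + R_list[[t]]
  }
  y <- as.numeric(t(obs))
  ch <- chol(big_S)
  z <- backsolve(ch, y - big_mu, transpose = TRUE)
  -0.5 * (2 * n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

## Planar observations -> lon/lat table ready for fit_ctcrw().
obs_to_lonlat <- function(obs, center = c(-157.5, 21),
                          t0 = t_utc("2024-01-01 00:00:00")) {
  ll <- divetag:::unproject_aeqd(obs$x, obs$y, center)
  data.frame(time = t0 + obs$time_h * 3600, lon = ll[, "lon"],
             lat = ll[, "lat"], semi_major_m = obs$semi_major_m,
             semi_minor_m = obs$semi_minor_m,
             orientation_deg = obs$orientation_deg,
             source = obs$source, stringsAsFactors = FALSE)
}

## Synthetic dive table for GAMM tests: gamma-distributed depths with a
## planted cyclic diel effect (optionally phase-shifted per animal), a
## linear current-magnitude effect, and a pure-noise covariate.
gamm_test_data <- function(n_animals = 8, n_per_animal = 250,
                           diel_amp = 0.3, phase_shift_sd = 0,
                           cur_slope = 0.5, gamma_shape = 10, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_animals), function(i) {
    n <- n_per_animal
    tod <- runif(n, 0, 24)
    cur <- runif(n, 0, 0.6)
    noise_cov <- runif(n, 0, 1)
    moon <- runif(n, 0, 2 * pi)
    shift <- rnorm(1, 0, phase_shift_sd)
    intercept <- rnorm(1, 0, 0.15)
    mu <- exp(log(200) + intercept +
                diel_amp * cos(2 * pi * (tod - 12 - shift) / 24) +
                cur_slope * (cur - 0.3))
    data.frame(animal_id = sprintf("G%02d", i), time_of_day = tod,
               moon_phase = moon, current_magnitude = cur,
               noise_cov = noise_cov,
               depth = rgamma(n, shape = gamma_shape,
                              rate = gamma_shape / mu))
  })
  do.call(rbind, rows)
}
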