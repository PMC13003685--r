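## Synthetic biologging studies with known ground truth: CTCRW tracks,
## error-degraded locations, behavior logs with planted diel / lunar /
## environmental effects and planted near-seafloor dives, island-slope
## bathymetry, and daily environmental fields.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe a plausible insular odontocete study: about ten
#' days of data per animal, OU-velocity movement with an autocorrelation
#' time of one hour and a typical speed of ~2 km/h, Argos-grade
#' kilometer-scale location error, a baseline of 0.45 dives per hour,
#' deeper dives at mid-day (diel amplitude 0.3 on the log-depth scale)
#' and near full moon, dives shallower where lagged surface
#' chlorophyll-a is high and deeper in stronger currents and deeper
#' mixed layers, and 15% of dives planted to terminate within 50 m of
#' the seafloor. Midwater (non-seafloor) dive depths are kept at least
#' `seafloor_clearance_m` above the seafloor so planted classes are
#' separable.
#'
#' @param n_animals number of tagged animals
#' @param duration_days days of data per animal
#' @param ctcrw_beta velocity autocorrelation rate, 1/h
#' @param ctcrw_sigma velocity diffusion scale, km/h^1.5
#' @param obs_rate observed locations per day
#' @param ellipse_scale_m typical location-error SD, m
#' @param dive_rate_base mean dives per hour
#' @param rate_diel_amplitude relative sinusoidal modulation of the dive
#'   intensity over the day (0 = homogeneous Poisson)
#' @param diel_amplitude amplitude of cos(2*pi*(hour - 12)/24) on log
#'   dive depth
#' @param lunar_amplitude amplitude of cos(moon phase) on log dive depth
#' @param env_effect_sizes named slopes on log depth per covariate
#'   (names among chl_log10_lag30, current_magnitude, mld)
#' @param depth_baseline_m median midwater dive depth, m
#' @param depth_sd_log lognormal SD of dive depth
#' @param duration_baseline_s median dive duration, s
#' @param duration_sd_log lognormal SD of dive duration
#' @param depth_duration_rho target Spearman correlation between dive
#'   depth and duration
#' @param frac_seafloor_dives proportion of dives planted near-seafloor
#' @param seafloor_clearance_m minimum gap between midwater dive depth
#'   and the seafloor, m
#' @param tag_depth_threshold_m,tag_duration_threshold_s onboard tag
#'   thresholds: shallower/shorter submergences are emitted as surface
#'   periods
#' @param dropout_fraction fraction of behavior-log time deleted in
#'   contiguous blocks (transmission gaps); default 0 (off)
#' @param domain lon/lat box c(lon_min, lon_max, lat_min, lat_max)
#' @param resolution raster resolution, degrees
#' @param start_date first day of the simulated study (UTC date)
#' @param seed integer seed; identical seeds give identical scenarios
#' @return list of class "scenario_config"
#' @export
scenario_config <- function(n_animals = 8, duration_days = 10,
                            ctcrw_beta = 1, ctcrw_sigma = 3,
                            obs_rate = 12, ellipse_scale_m = 800,
                            dive_rate_base = 0.45,
                            rate_diel_amplitude = 0.5,
                            diel_amplitude = 0.3, lunar_amplitude = 0.1,
                            env_effect_sizes = c(chl_log10_lag30 = -0.3,
                                                 current_magnitude = 0.5,
                                                 mld = 0.005),
                            depth_baseline_m = 200, depth_sd_log = 0.5,
                            duration_baseline_s = 330,
                            duration_sd_log = 0.4,
                            depth_duration_rho = 0.7,
                            frac_seafloor_dives = 0.15,
                            seafloor_clearance_m = 300,
                            tag_depth_threshold_m = 30,
                            tag_duration_threshold_s = 60,
                            dropout_fraction = 0,
                            domain = c(-159, -155, 19, 23),
                            resolution = 0.025,
                            start_date = as.Date("2024-01-01"),
                            seed = 1) {
  cfg <- as.list(environment())
  check_that(all(c(cfg$ctcrw_beta, cfg$ctcrw_sigma, cfg$obs_rate,
                   cfg$dive_rate_base, cfg$resolution) > 0),
             "rates and scales must be strictly positive")
  check_that(cfg$frac_seafloor_dives >= 0 && cfg$frac_seafloor_dives <= 1,
             "frac_seafloor_dives must be in [0, 1]")
  check_that(cfg$ellipse_scale_m >= 0, "ellipse_scale_m must be >= 0")
  structure(cfg, class = "scenario_config")
}

#' Simulate a planar CTCRW track
#'
#' Exact simulation of the integrated-OU movement process: velocity per
#' axis is a stationary OU process (autocorrelation exp(-beta * dt)),
#' position its integral. Initial velocity is drawn from the stationary
#' distribution so the whole path is stationary in velocity.
#'
#' @param beta 1/h, velocity autocorrelation rate (> 0)
#' @param sigma m/h^1.5, velocity diffusion scale (> 0)
#' @param duration_h hours to simulate
#' @param dt_h time step in hours (default 1 minute)
#' @param seed integer seed
#' @param x0 starting position (m), default origin
#' @return data.frame of class "true_path": time_h, x, y, vx, vy
#' @export
simulate_ctcrw_track <- function(beta, sigma, duration_h, dt_h = 1 / 60,
                                 seed = 1, x0 = c(0, 0)) {
  check_that(beta > 0, "beta must be > 0")
  check_that(sigma > 0, "sigma must be > 0")
  check_that(dt_h > 0, "dt must be > 0")
  set.seed(seed)
  n <- floor(duration_h / dt_h) + 1
  d <- ou_discretize(beta, sigma, dt_h)
  ## Cholesky of the per-step 2x2 process covariance (position, velocity)
  L <- t(chol(d$Q + diag(1e-12, 2)))
  vel_sd <- sigma / sqrt(2 * beta)
  x <- numeric(n); y <- numeric(n); vx <- numeric(n); vy <- numeric(n)
  x[1] <- x0[1]; y[1] <- x0[2]
  vx[1] <- stats::rnorm(1, 0, vel_sd); vy[1] <- stats::rnorm(1, 0, vel_sd)
  zx <- matrix(stats::rnorm(2 * (n - 1)), 2)
  zy <- matrix(stats::rnorm(2 * (n - 1)), 2)
  ex <- L %*% zx; ey <- L %*% zy
  a <- d$F[2, 2]; g <- d$F[1, 2]
  for (t in 2:n) {
    x[t] <- x[t - 1] + g * vx[t - 1] + ex[1, t - 1]
    vx[t] <- a * vx[t - 1] + ex[2, t - 1]
    y[t] <- y[t - 1] + g * vy[t - 1] + ey[1, t - 1]
    vy[t] <- a * vy[t - 1] + ey[2, t - 1]
  }
  structure(data.frame(time_h = (seq_len(n) - 1) * dt_h,
                       x = x, y = y, vx = vx, vy = vy),
            class = c("true_path", "data.frame"),
            beta = beta, sigma = sigma, dt_h = dt_h)
}

#' Degrade a true path to error-prone observed locations
#'
#' Observation times are a Poisson process at `obs_rate` per day over
#' the path's span; each observed position is the (linearly
#' interpolated) true position plus zero-mean Gaussian noise with a
#' random anisotropic covariance: the major-axis SD is lognormal around
#' `ellipse_scale_m`, the minor-axis SD a Uniform(0.3, 1) multiple of
#' it, orientation uniform. The generating covariance is reported with
#' each record as a 95% error ellipse (semi-axes sqrt(5.991) times the
#' SDs), matching the convention used when fitting.
#'
#' @param path a [simulate_ctcrw_track()] result
#' @param obs_rate locations per day (> 0)
#' @param ellipse_scale_m typical error SD in meters (0 = error-free)
#' @param seed integer seed
#' @return data.frame: time_h, x, y, semi_major_m, semi_minor_m,
#'   orientation_deg, source, true_x, true_y
#' @export
degrade_to_observations <- function(path, obs_rate, ellipse_scale_m,
                                    seed = 1) {
  check_that(obs_rate > 0, "obs_rate must be > 0")
  check_that(nrow(path) > 1, "path is empty")
  set.seed(seed)
  span_h <- max(path$time_h)
  n_obs <- stats::rpois(1, obs_rate * span_h / 24)
  t_obs <- sort(stats::runif(n_obs, 0, span_h))
  tx <- stats::approx(path$time_h, path$x, xout = t_obs)$y
  ty <- stats::approx(path$time_h, path$y, xout = t_obs)$y
  if (ellipse_scale_m > 0) {
    sd_a <- ellipse_scale_m * exp(stats::rnorm(n_obs, 0, 0.3))
    sd_b <- sd_a * stats::runif(n_obs, 0.3, 1)
    theta <- stats::runif(n_obs, 0, 180)
    th <- theta * pi / 180
    z1 <- stats::rnorm(n_obs); z2 <- stats::rnorm(n_obs)
    ## noise = sd_a * z1 * u + sd_b * z2 * w, u = major direction
    ex <- sd_a * z1 * sin(th) + sd_b * z2 * cos(th)
    ey <- sd_a * z1 * cos(th) - sd_b * z2 * sin(th)
  } else {
    sd_a <- sd_b <- rep(0, n_obs); theta <- rep(0, n_obs)
    ex <- ey <- rep(0, n_obs)
  }
  data.frame(time_h = t_obs, x = tx + ex, y = ty + ey,
             semi_major_m = sqrt(CHI2_95_DF2) * sd_a,
             semi_minor_m = sqrt(CHI2_95_DF2) * sd_b,
             orientation_deg = theta, source = "argos",
             true_x = tx, true_y = ty)
}

#' Build synthetic bathymetry and environmental rasters
#'
#' Bathymetry is a smooth island-slope surface: depth 0 on a central
#' island, shelving with a tanh ramp to an abyssal depth, with a
#' shallow bank feature and a gentle smooth undulation. The
#' environmental stack holds daily chlorophyll-a (lognormal, with a
#' land-overlap flag layer), SST, mixed layer depth, and zonal /
#' meridional currents as smooth random fields evolving as AR(1) in
#' time.
#'
#' @param domain c(lon_min, lon_max, lat_min, lat_max)
#' @param resolution degrees (> 0)
#' @param n_days number of daily slices
#' @param start_date Date of the first slice
#' @param seed integer seed
#' @param island_radius_km island radius, default 30
#' @param ramp_km horizontal scale of the island slope, default 60
#' @param abyssal_depth_m default 2500
#' @return list(bathy = grid_raster, env = raster_stack)
#' @export
build_rasters <- function(domain, resolution = 0.025, n_days = 45,
                          start_date = as.Date("2024-01-01"), seed = 1,
                          island_radius_km = 30, ramp_km = 60,
                          abyssal_depth_m = 2500) {
  check_that(resolution > 0, "resolution must be > 0")
  check_that(domain[2] > domain[1] && domain[4] > domain[3],
             "domain box is degenerate")
  set.seed(seed)
  lon <- seq(domain[1], domain[2], by = resolution)
  lat <- seq(domain[3], domain[4], by = resolution)
  c_lon <- mean(domain[1:2]); c_lat <- mean(domain[3:4])
  km_per_deg <- 111.32
  gx <- outer((lon - c_lon) * km_per_deg * cos(c_lat * pi / 180),
              rep(1, length(lat)))
  gy <- outer(rep(1, length(lon)), (lat - c_lat) * km_per_deg)
  dist_km <- sqrt(gx^2 + gy^2)
  depth <- abyssal_depth_m * pmax(tanh((dist_km - island_radius_km) / ramp_km), 0)
  ## shallow bank south-west of the island
  bank <- 0.75 * depth * exp(-((gx + 80)^2 + (gy + 60)^2) / (2 * 25^2))
  depth <- depth - bank
  ## gentle smooth undulation (low-frequency cosine field)
  und <- 60 * cos(2 * pi * gx / 180 + stats::runif(1, 0, 2 * pi)) *
    cos(2 * pi * gy / 150 + stats::runif(1, 0, 2 * pi))
  depth <- pmax(depth + und * (depth > 0), 0)
  land <- depth <= 0
  bathy <- grid_raster(lon, lat, depth, flag = land, name = "seafloor_depth")

  smooth_field <- function(phase_scale = 1) {
    f <- matrix(0, length(lon), length(lat))
    for (k in 1:4) {
      fx <- stats::runif(1, 0.5, 2) / 200
      fy <- stats::runif(1, 0.5, 2) / 200
      ph <- stats::runif(1, 0, 2 * pi)
      f <- f + stats::rnorm(1, 0, 1 / k) *
        cos(2 * pi * (fx * gx + fy * gy) + ph * phase_scale)
    }
    f / 2
  }
  dates <- start_date + seq_len(n_days) - 1
  make_layer <- function(transform) {
    base <- smooth_field()
    innov_sd <- 0.3
    arr <- array(NA_real_, c(length(lon), length(lat), n_days))
    f <- base
    for (d in seq_len(n_days)) {
      f <- 0.9 * f + innov_sd * smooth_field()
      arr[, , d] <- transform(f)
    }
    arr
  }
  layers <- list(
    chl = make_layer(function(f) exp(log(0.08) + 0.6 * f)),
    sst = make_layer(function(f) 25 + 1.5 * f),
    mld = make_layer(function(f) pmax(40 + 15 * f, 5)),
    u = make_layer(function(f) 0.25 * f),
    v = make_layer(function(f) 0.25 * f)
  )
  env <- raster_stack(lon, lat, dates, layers, flag = land)
  list(bathy = bathy, env = derive_fields(env))
}

## Reflect planar coordinates into [-half, half] (used to confine
## simulated animals to the raster domain, emulating a home range).
reflect_into <- function(z, half) {
  period <- 4 * half
  z <- ((z + half) %% period + period) %% period
  ifelse(z <= 2 * half, z - half, 3 * half - z)
}

#' Simulate a behavior log along a true path
#'
#' Dive start times follow an inhomogeneous Poisson process with
#' sinusoidal diel intensity (mean `dive_rate_base` per hour, relative
#' amplitude `rate_diel_amplitude`, peak at mid-day HST). Log dive
#' depth is baseline + diel_amplitude * cos(2*pi*(hour - 12)/24) +
#' lunar_amplitude * cos(moon phase) + sum(slope * covariate) +
#' Gaussian noise; durations share a Gaussian copula with depth at rank
#' correlation `depth_duration_rho`. A fraction `frac_seafloor_dives`
#' of dives is planted at the seafloor depth under the true position
#' minus Uniform(0, 50) m; all other dives are kept at least
#' `seafloor_clearance_m` above the seafloor. Submergences below the
#' tag's onboard thresholds are emitted as surface records (onboard
#' truncation); reported depth/duration minima and maxima bracket the
#' true value by +/-1%, so their mean recovers it exactly.
#'
#' @param path [simulate_ctcrw_track()] result
#' @param cfg [scenario_config()]
#' @param bathy,env rasters from [build_rasters()]
#' @param seed integer seed
#' @param t0 POSIXct deployment start (UTC)
#' @param center projection center c(lon, lat) mapping path meters to
#'   geography
#' @param animal_id identifier
#' @return list(records = behavior record data.frame,
#'   truth = per-dive truth table)
#' @export
simulate_behavior_log <- function(path, cfg, bathy, env, seed = 1,
                                  t0 = as.POSIXct("2024-01-01", tz = "UTC"),
                                  center = NULL, animal_id = "A01") {
  set.seed(seed)
  center <- center %||% c(mean(bathy$lon), mean(bathy$lat))
  span_h <- max(path$time_h)

  ## --- dive start times: inhomogeneous Poisson by thinning ---
  lam_max <- cfg$dive_rate_base * (1 + cfg$rate_diel_amplitude)
  n_cand <- stats::rpois(1, lam_max * span_h)
  t_cand <- sort(stats::runif(n_cand, 0, span_h))
  hour_cand <- hst_hour(t0 + t_cand * 3600)
  lam <- cfg$dive_rate_base *
    (1 + cfg$rate_diel_amplitude * cos(2 * pi * (hour_cand - 12) / 24))
  keep <- stats::runif(n_cand) < lam / lam_max
  t_dive <- t_cand[keep]

  ## --- true positions and covariates at dive times ---
  px <- stats::approx(path$time_h, path$x, xout = t_dive)$y
  py <- stats::approx(path$time_h, path$y, xout = t_dive)$y
  ll <- unproject_aeqd(px, py, center)
  times <- t0 + t_dive * 3600
  in_dom <- !is.na(nearest_index(bathy$lon, ll[, "lon"])) &
    !is.na(nearest_index(bathy$lat, ll[, "lat"]))
  if (!all(in_dom)) {
    stop("simulated path leaves the raster domain at t = ",
         round(t_dive[which(!in_dom)[1]], 2), " h", call. = FALSE)
  }
  seafloor <- extract_at(bathy, ll[, "lon"], ll[, "lat"])$value
  cov_tbl <- data.frame(row.names = seq_along(t_dive))
  for (nm in names(cfg$env_effect_sizes)) {
    layer <- switch(nm, chl_log10_lag30 = "chl_log10", nm)
    lag <- if (nm == "chl_log10_lag30") 30 else 0
    v <- extract_at(env, ll[, "lon"], ll[, "lat"], times, layer,
                    lag_days = lag)$value
    if (anyNA(v)) {
      stop("simulated path leaves the environmental raster domain at t = ",
           round(t_dive[which(is.na(v))[1]], 2), " h", call. = FALSE)
    }
    cov_tbl[[nm]] <- v
  }

  ## --- planted structural effects on log depth ---
  hour <- hst_hour(times)
  phase <- moon_phase(times)
  lp <- log(cfg$depth_baseline_m) +
    cfg$diel_amplitude * cos(2 * pi * (hour - 12) / 24) +
    cfg$lunar_amplitude * cos(phase)
  for (nm in names(cfg$env_effect_sizes)) {
    v <- cov_tbl[[nm]]
    lp <- lp + cfg$env_effect_sizes[[nm]] * (v - mean(v))
  }
  z_depth <- stats::rnorm(length(t_dive))
  log_depth <- lp + cfg$depth_sd_log * z_depth
  depth <- exp(log_depth)

  ## near-seafloor planting, midwater clearance capping
  is_sf <- stats::runif(length(t_dive)) < cfg$frac_seafloor_dives
  depth[is_sf] <- pmax(20, seafloor[is_sf] -
                         stats::runif(sum(is_sf), 0, 50))
  cap <- pmax(25, seafloor - cfg$seafloor_clearance_m)
  depth[!is_sf] <- pmin(depth[!is_sf], cap[!is_sf])

  ## --- durations: Gaussian copula with (standardized) log depth ---
  rho_p <- 2 * sin(pi * cfg$depth_duration_rho / 6)
  zd <- (log(depth) - mean(log(depth))) / stats::sd(log(depth))
  z2 <- rho_p * zd + sqrt(1 - rho_p^2) * stats::rnorm(length(t_dive))
  duration <- exp(log(cfg$duration_baseline_s) + cfg$duration_sd_log * z2)
  duration <- pmax(30, duration)

  ## drop dives overlapping the previous dive
  ok <- rep(TRUE, length(t_dive))
  if (length(t_dive) > 1) {
    last_end <- t_dive[1] + duration[1] / 3600
    for (i in 2:length(t_dive)) {
      if (t_dive[i] <= last_end + 1 / 60) ok[i] <- FALSE
      else last_end <- t_dive[i] + duration[i] / 3600
    }
  }

  bottom_frac <- stats::rbeta(length(t_dive), 4, 4)
  shape <- ifelse(bottom_frac > 0.5, "square",
                  ifelse(bottom_frac > 0.2, "u", "v"))

  truth <- data.frame(
    animal_id = animal_id,
    time = times, lon = ll[, "lon"], lat = ll[, "lat"],
    x = px, y = py, depth = depth, duration = duration,
    hour = hour, moon_phase = phase,
    seafloor_depth = seafloor, is_near_seafloor = is_sf,
    shape = shape, retained = ok
  )
  truth <- cbind(truth, cov_tbl)
  truth <- truth[ok, ]
  rownames(truth) <- NULL

  ## onboard truncation: below-threshold submergences become surface time
  emitted <- truth$depth >= cfg$tag_depth_threshold_m &
    truth$duration >= cfg$tag_duration_threshold_s
  truth$emitted <- emitted

  ## --- assemble alternating dive/surface records ---
  ev_start <- as.numeric(truth$time)
  ev_end <- ev_start + truth$duration
  dep_start <- as.numeric(t0); dep_end <- as.numeric(t0) + span_h * 3600
  recs <- list()
  cursor <- dep_start
  for (i in seq_len(nrow(truth))) {
    if (!emitted[i]) next # swallowed into the surrounding surface period
    if (ev_start[i] > cursor) {
      recs[[length(recs) + 1]] <- data.frame(
        kind = "surface", start = cursor, end = ev_start[i],
        depth = NA_real_, duration = ev_start[i] - cursor,
        shape = "none", truth_row = NA_integer_)
    }
    recs[[length(recs) + 1]] <- data.frame(
      kind = "dive", start = ev_start[i], end = ev_end[i],
      depth = truth$depth[i], duration = truth$duration[i],
      shape = truth$shape[i], truth_row = i)
    cursor <- ev_end[i]
  }
  if (cursor < dep_end) {
    recs[[length(recs) + 1]] <- data.frame(
      kind = "surface", start = cursor, end = dep_end,
      depth = NA_real_, duration = dep_end - cursor,
      shape = "none", truth_row = NA_integer_)
  }
  rec <- do.call(rbind, recs)

  ## optional dropout: delete contiguous blocks of records
  if (cfg$dropout_fraction > 0) {
    target <- cfg$dropout_fraction * (dep_end - dep_start)
    deleted <- 0
    attempts <- 0
    while (deleted < target && nrow(rec) > 4 && attempts < 500) {
      attempts <- attempts + 1
      i0 <- sample.int(nrow(rec) - 1, 1)
      i1 <- min(nrow(rec), i0 + sample.int(3, 1) - 1)
      block <- sum(rec$duration[i0:i1])
      if (deleted + block > target * 1.05) next # keep close to target
      deleted <- deleted + block
      rec <- rec[-(i0:i1), , drop = FALSE]
    }
  }

  ## reported min/max bracket truth by +/-1%; mean of bracket == truth
  out <- data.frame(
    animal_id = animal_id, kind = rec$kind,
    start = .POSIXct(rec$start, tz = "UTC"),
    end = .POSIXct(rec$end, tz = "UTC"),
    depth_min = ifelse(rec$kind == "dive", rec$depth * 0.99, NA_real_),
    depth_max = ifelse(rec$kind == "dive", rec$depth * 1.01, NA_real_),
    dur_min = rec$duration * 0.99, dur_max = rec$duration * 1.01,
    shape = rec$shape, truth_row = rec$truth_row,
    stringsAsFactors = FALSE
  )
  out$depth <- (out$depth_min + out$depth_max) / 2
  out$duration <- (out$dur_min + out$dur_max) / 2
  ## surface records are bounded by clock time, not sensor summaries
  out$dur_min[out$kind == "surface"] <- NA_real_
  out$dur_max[out$kind == "surface"] <- NA_real_
  out$duration[out$kind == "surface"] <-
    as.numeric(out$end[out$kind == "surface"]) -
    as.numeric(out$start[out$kind == "surface"])
  list(records = out, truth = truth)
}

#' Simulate a complete synthetic tagging study
#'
#' Builds rasters, simulates one CTCRW track per animal (confined to
#' the raster domain by reflection, emulating a home range), degrades
#' each to observed locations, generates behavior logs with planted
#' effects, and returns everything with the ground truth.
#'
#' @param cfg a [scenario_config()]
#' @return list of class "synthetic_scenario": cfg, bathy, env, and
#'   per-animal list with true path (planar + lon/lat), observations
#'   (lon/lat + ellipses), behavior records, truth table, metadata
#' @export
simulate_scenario <- function(cfg = scenario_config()) {
  ras <- build_rasters(cfg$domain, cfg$resolution,
                       n_days = cfg$duration_days + 35,
                       start_date = cfg$start_date - 32,
                       seed = child_seed(cfg$seed, 1))
  center <- c(mean(cfg$domain[1:2]), mean(cfg$domain[3:4]))
  km_per_deg <- 111.32
  half_x <- (cfg$domain[2] - cfg$domain[1]) / 2 * km_per_deg *
    cos(center[2] * pi / 180) * 1000 * 0.85
  half_y <- (cfg$domain[4] - cfg$domain[3]) / 2 * km_per_deg * 1000 * 0.85
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")

  animals <- list()
  sexes <- c("M", "F", "U")
  for (i in seq_len(cfg$n_animals)) {
    id <- sprintf("SYN%02d", i)
    ## deployments start offshore, on a ring clear of the central island
    ang <- 2 * pi * (i - 0.5) / cfg$n_animals
    x0 <- 110e3 * c(cos(ang), sin(ang))
    path <- simulate_ctcrw_track(cfg$ctcrw_beta, cfg$ctcrw_sigma * 1000,
                                 duration_h = cfg$duration_days * 24,
                                 seed = child_seed(cfg$seed, 100 + i),
                                 x0 = x0)
    path$x <- reflect_into(path$x, half_x)
    path$y <- reflect_into(path$y, half_y)
    obs <- degrade_to_observations(path, cfg$obs_rate, cfg$ellipse_scale_m,
                                   seed = child_seed(cfg$seed, 200 + i))
    obs_ll <- unproject_aeqd(obs$x, obs$y, center)
    obs$lon <- obs_ll[, "lon"]; obs$lat <- obs_ll[, "lat"]
    obs$time <- t0 + obs$time_h * 3600
    obs$animal_id <- id
    log <- simulate_behavior_log(path, cfg, ras$bathy, ras$env,
                                 seed = child_seed(cfg$seed, 300 + i),
                                 t0 = t0, center = center, animal_id = id)
    path_ll <- unproject_aeqd(path$x, path$y, center)
    path$lon <- path_ll[, "lon"]; path$lat <- path_ll[, "lat"]
    animals[[id]] <- list(
      path = path, observations = obs,
      records = log$records, truth = log$truth,
      metadata = data.frame(
        animal_id = id, population = if (i %% 2) "insular" else "open-ocean",
        sex = sexes[1 + (i %% 3)], age_class = "adult",
        fin_base_cm = round(55 + 13 * (i - 1) / max(1, cfg$n_animals - 1), 1))
    )
  }
  structure(list(cfg = cfg, bathy = ras$bathy, env = ras$env,
                 center = center, t0 = t0, animals = animals),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  n_dive <- sum(vapply(x$animals, function(a) sum(a$records$kind == "dive"),
                       numeric(1)))
  cat("Synthetic scenario: ", length(x$animals), " animals, ",
      x$cfg$duration_days, " days each, ", n_dive,
      " emitted dive records (seed ", x$cfg$seed, ")\n", sep = "")
  invisible(x)
}
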