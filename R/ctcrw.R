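## Continuous-time correlated random walk (CTCRW) movement model:
## integrated Ornstein-Uhlenbeck velocity per axis, fit to error-prone
## locations by Kalman filtering; smoothing, prediction, and multiple
## imputation by forward-filter backward-sampling.
##
## State per axis is (position, velocity) with
##   dv = -beta * v * dt + sigma * dW,   dx = v * dt.
## Exact discretization over a step of length dt:
##   v' = a v + zeta,          a = exp(-beta dt)
##   x' = x + v (1 - a)/beta + xi
## with process covariance
##   var(zeta) = sigma^2 (1 - a^2) / (2 beta)
##   var(xi)   = sigma^2/beta^2 (dt - 2(1-a)/beta + (1-a^2)/(2 beta))
##   cov(xi,zeta) = sigma^2/(2 beta^2) (1 - 2a + a^2)
## Units: meters and hours internally; beta in 1/h, sigma in m/h^1.5.

## chi-square(2) 95% quantile, used for the 95%-ellipse convention
CHI2_95_DF2 <- 5.991465

#' Exact discretization of the integrated OU process (one axis)
#' @return list with F (2x2) and Q (2x2): state order (position, velocity)
#' @keywords internal
ou_discretize <- function(beta, sigma, dt) {
  a <- exp(-beta * dt)
  g <- (1 - a) / beta
  qvv <- sigma^2 * (1 - a^2) / (2 * beta)
  qxx <- sigma^2 / beta^2 * (dt - 2 * g + (1 - a^2) / (2 * beta))
  qxv <- sigma^2 / (2 * beta^2) * (1 - a)^2
  list(F = matrix(c(1, 0, g, a), 2, 2),
       Q = matrix(c(qxx, qxv, qxv, qvv), 2, 2))
}

## 4-state versions (x, vx, y, vy): block diagonal over axes.
ou_discretize4 <- function(beta, sigma, dt) {
  d <- ou_discretize(beta, sigma, dt)
  F4 <- matrix(0, 4, 4); Q4 <- matrix(0, 4, 4)
  F4[1:2, 1:2] <- d$F; F4[3:4, 3:4] <- d$F
  Q4[1:2, 1:2] <- d$Q; Q4[3:4, 3:4] <- d$Q
  list(F = F4, Q = Q4)
}

#' Error-ellipse to observation covariance
#'
#' Stored ellipses are treated as 95% ellipses: the semi-axes are scaled
#' by 1/sqrt(5.991) to standard deviations, rotated by the orientation
#' (degrees clockwise from north of the semi-major axis). Semi-axes are
#' floored at `floor_m` meters to avoid degenerate covariances.
#'
#' @keywords internal
ellipse_to_cov <- function(semi_major, semi_minor, orientation_deg,
                           floor_m = 10) {
  a <- pmax(semi_major, floor_m) / sqrt(CHI2_95_DF2)
  b <- pmax(semi_minor, floor_m) / sqrt(CHI2_95_DF2)
  th <- orientation_deg * pi / 180
  u1 <- sin(th); u2 <- cos(th)  # major-axis direction (east, north)
  lapply(seq_along(a), function(i) {
    u <- c(u1[i], u2[i]); w <- c(u2[i], -u1[i])
    a[i]^2 * tcrossprod(u) + b[i]^2 * tcrossprod(w)
  })
}

## Core Kalman filter. obs: n x 2 matrix (NA rows = no observation),
## times: hours (nondecreasing), R_list: per-row 2x2 covariance (ignored
## for NA rows). Returns loglik and, if keep_states, filtered/predicted
## moments and transition matrices for smoothing/sampling.
ctcrw_filter <- function(obs, times, R_list, beta, sigma,
                         init_xy, init_pos_var = 1e10,
                         keep_states = FALSE) {
  n <- nrow(obs)
  vel_var <- sigma^2 / (2 * beta)
  m <- c(init_xy[1], 0, init_xy[2], 0)
  P <- diag(c(init_pos_var, vel_var, init_pos_var, vel_var))
  loglik <- 0
  if (keep_states) {
    m_pred <- matrix(NA_real_, n, 4); m_filt <- matrix(NA_real_, n, 4)
    P_pred <- vector("list", n); P_filt <- vector("list", n)
    F_list <- vector("list", n)
  }
  dts <- c(0, diff(times))
  for (t in seq_len(n)) {
    if (dts[t] > 0) {
      d <- ou_discretize4(beta, sigma, dts[t])
      m <- d$F %*% m
      P <- d$F %*% P %*% t(d$F) + d$Q
      if (keep_states) F_list[[t]] <- d$F
    } else if (keep_states) {
      F_list[[t]] <- diag(4)
    }
    m <- as.numeric(m)
    if (keep_states) { m_pred[t, ] <- m; P_pred[[t]] <- P }
    y <- obs[t, ]
    if (!anyNA(y)) {
      e <- c(y[1] - m[1], y[2] - m[3])
      S <- P[c(1, 3), c(1, 3)] + R_list[[t]]
      det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
      Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det_s
      K <- P[, c(1, 3)] %*% Sinv
      m <- m + as.numeric(K %*% e)
      P <- P - K %*% P[c(1, 3), ]
      P <- (P + t(P)) / 2
      loglik <- loglik - log(2 * pi) - 0.5 * log(det_s) -
        0.5 * sum(e * (Sinv %*% e))
    }
    if (keep_states) { m_filt[t, ] <- m; P_filt[[t]] <- P }
  }
  out <- list(loglik = loglik)
  if (keep_states) {
    out <- c(out, list(m_pred = m_pred, P_pred = P_pred,
                       m_filt = m_filt, P_filt = P_filt, F_list = F_list,
                       times = times))
  }
  out
}

## Rauch-Tung-Striebel smoother over a kept-state filter run.
ctcrw_smooth <- function(flt) {
  n <- nrow(flt$m_filt)
  m_s <- flt$m_filt; P_s <- flt$P_filt
  J_list <- vector("list", n)
  if (n > 1) {
    for (t in (n - 1):1) {
      Fn <- flt$F_list[[t + 1]]
      Pp <- flt$P_pred[[t + 1]]
      J <- flt$P_filt[[t]] %*% t(Fn) %*% solve(Pp)
      m_s[t, ] <- flt$m_filt[t, ] +
        as.numeric(J %*% (m_s[t + 1, ] - flt$m_pred[t + 1, ]))
      P_s[[t]] <- flt$P_filt[[t]] + J %*% (P_s[[t + 1]] - Pp) %*% t(J)
      P_s[[t]] <- (P_s[[t]] + t(P_s[[t]])) / 2
      J_list[[t]] <- J
    }
  }
  list(m_smooth = m_s, P_smooth = P_s, J_list = J_list)
}

## Draw one path from the joint smoothing distribution
## (forward-filter backward-sampling).
ctcrw_ffbs_draw <- function(flt) {
  n <- nrow(flt$m_filt)
  draw <- matrix(NA_real_, n, 4)
  draw[n, ] <- mvn_draw(flt$m_filt[n, ], flt$P_filt[[n]])
  if (n > 1) {
    for (t in (n - 1):1) {
      Fn <- flt$F_list[[t + 1]]
      Pp <- flt$P_pred[[t + 1]]
      J <- flt$P_filt[[t]] %*% t(Fn) %*% solve(Pp)
      mu <- flt$m_filt[t, ] + as.numeric(J %*% (draw[t + 1, ] - flt$m_pred[t + 1, ]))
      V <- flt$P_filt[[t]] - J %*% Pp %*% t(J)
      draw[t, ] <- mvn_draw(mu, (V + t(V)) / 2)
    }
  }
  draw
}

mvn_draw <- function(mu, V) {
  p <- length(mu)
  ev <- eigen(V, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  mu + as.numeric(ev$vectors %*% (sqrt(lam) * stats::rnorm(p)))
}

#' Prefilter observed locations on speed and turn-angle spikes
#'
#' Iteratively removes locations implying an unrealistic straight-line
#' speed from the previous retained location (removing the later point
#' of the first violating segment) and out-and-back spikes: points where
#' the track turns by more than (180 - spike_angle) degrees with both
#' legs longer than `spike_min_leg_m`. Repeats until no violation
#' remains, so the filter is idempotent.
#'
#' @param obs data.frame with time (POSIXct), lon, lat (+ any columns)
#' @param max_speed m/s, default 7.5
#' @param spike_angle degrees: internal angles below this are spikes
#'   (default 15)
#' @param spike_min_leg_m both legs must exceed this for the spike test
#'   (default 2500)
#' @return the retained rows of `obs`
#' @export
prefilter_locations <- function(obs, max_speed = 7.5, spike_angle = 15,
                                spike_min_leg_m = 2500) {
  o <- obs[order(as.numeric(obs$time)), , drop = FALSE]
  repeat {
    n <- nrow(o)
    if (n < 3) stop("fewer than 3 locations remain after filtering",
                    call. = FALSE)
    p <- cbind(o$lon, o$lat)
    d <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
    dt <- diff(as.numeric(o$time))
    speed <- d / pmax(dt, 1)
    bad_speed <- which(speed > max_speed)
    if (length(bad_speed)) {
      o <- o[-(bad_speed[1] + 1), , drop = FALSE]
      next
    }
    ## spike test: angle at interior points
    if (n >= 3) {
      leg1 <- d[-(n - 1)]
      leg2 <- d[-1]
      b1 <- geosphere::bearing(p[2:(n - 1), , drop = FALSE],
                               p[1:(n - 2), , drop = FALSE])
      b2 <- geosphere::bearing(p[2:(n - 1), , drop = FALSE],
                               p[3:n, , drop = FALSE])
      ang <- abs(((b1 - b2 + 180) %% 360) - 180)
      spikes <- which(ang < spike_angle & leg1 > spike_min_leg_m &
                        leg2 > spike_min_leg_m)
      if (length(spikes)) {
        o <- o[-(spikes[1] + 1), , drop = FALSE]
        next
      }
    }
    break
  }
  rownames(o) <- NULL
  o
}

#' Fit a continuous-time correlated random walk to observed locations
#'
#' Maximizes the Kalman-filter likelihood of the integrated-OU
#' state-space model over (beta, sigma) on the log scale, with three
#' dispersed restarts. Locations are projected to planar meters with an
#' azimuthal equidistant projection centered on the median observed
#' location; observation noise comes from each record's 95% error
#' ellipse (GPS records without ellipses get a circular 95% ellipse of
#' `gps_ellipse_m`).
#'
#' @param obs data.frame: time (POSIXct UTC), lon, lat, and optionally
#'   semi_major_m, semi_minor_m, orientation_deg, source
#' @param gps_ellipse_m 95% ellipse radius for GPS records lacking
#'   ellipses, default 50
#' @param ellipse_floor_m minimum semi-axis, default 10
#' @return object of class "ctcrw_fit": beta (1/h), sigma (m/h^1.5),
#'   loglik, projection center, planar observations, and optimizer info
#' @export
fit_ctcrw <- function(obs, gps_ellipse_m = 50, ellipse_floor_m = 10) {
  check_that(nrow(obs) >= 20, "need at least 20 locations")
  o <- obs[order(as.numeric(obs$time)), , drop = FALSE]
  span_h <- diff(range(as.numeric(o$time))) / 3600
  check_that(span_h >= 24, "locations must span at least one day")

  center <- c(stats::median(o$lon), stats::median(o$lat))
  xy <- project_aeqd(o$lon, o$lat, center)
  times_h <- (as.numeric(o$time) - as.numeric(o$time[1])) / 3600

  sm <- o$semi_major_m %||% rep(NA_real_, nrow(o))
  sn <- o$semi_minor_m %||% rep(NA_real_, nrow(o))
  or <- o$orientation_deg %||% rep(0, nrow(o))
  src <- o$source %||% rep("argos", nrow(o))
  sm[is.na(sm)] <- ifelse(src[is.na(sm)] == "gps", gps_ellipse_m, 500)
  sn[is.na(sn)] <- ifelse(src[is.na(sn)] == "gps", gps_ellipse_m, 500)
  or[is.na(or)] <- 0
  R_list <- ellipse_to_cov(sm, sn, or, floor_m = ellipse_floor_m)

  nll <- function(par) {
    beta <- exp(par[1]); sigma <- exp(par[2])
    if (!is.finite(beta) || !is.finite(sigma)) return(1e12)
    ll <- ctcrw_filter(xy, times_h, R_list, beta, sigma,
                       init_xy = xy[1, ])$loglik
    if (!is.finite(ll)) 1e12 else -ll
  }

  ## data-driven starting scale: RMS speed between consecutive locations
  dt <- pmax(diff(times_h), 1 / 60)
  v <- sqrt(rowSums(diff(xy)^2)) / dt
  v0 <- max(stats::median(v), 10)
  starts <- list(c(log(1), log(v0 * sqrt(2))),
                 c(log(0.2), log(v0)),
                 c(log(5), log(v0 * 4)))
  best <- NULL
  for (s in starts) {
    op <- stats::optim(s, nll, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (!is.finite(best$value) || best$value >= 1e12) {
    stop("CTCRW optimization failed to find a finite likelihood; ",
         "optimizer value = ", best$value, call. = FALSE)
  }
  beta <- exp(best$par[1]); sigma <- exp(best$par[2])
  structure(list(beta = beta, sigma = sigma, loglik = -best$value,
                 center = center, xy = xy, times_h = times_h,
                 R_list = R_list, time_origin = o$time[1],
                 times = o$time, convergence = best$convergence,
                 animal_id = o$animal_id[1] %||% "unknown"),
            class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("CTCRW fit: beta = ", signif(x$beta, 4), " /h, sigma = ",
      signif(x$sigma / 1000, 4), " km/h^1.5, loglik = ",
      round(x$loglik, 1), ", n = ", nrow(x$xy), " locations\n", sep = "")
  invisible(x)
}

## Build the merged (observation + requested) time grid and run the
## filter with kept states. Returns the filter run, smoothed moments,
## and the indices of the requested times in the grid.
ctcrw_grid_run <- function(fit, times) {
  t_req_h <- (as.numeric(parse_utc(times)) - as.numeric(fit$time_origin)) / 3600
  all_h <- c(fit$times_h, t_req_h)
  is_obs <- c(rep(TRUE, length(fit$times_h)), rep(FALSE, length(t_req_h)))
  ord <- order(all_h, !is_obs)
  all_h <- all_h[ord]; is_obs <- is_obs[ord]
  obs_idx <- cumsum(is_obs)
  obs_mat <- matrix(NA_real_, length(all_h), 2)
  obs_mat[is_obs, ] <- fit$xy
  R_all <- vector("list", length(all_h))
  R_all[is_obs] <- fit$R_list
  flt <- ctcrw_filter(obs_mat, all_h, R_all, fit$beta, fit$sigma,
                      init_xy = fit$xy[1, ], keep_states = TRUE)
  ## positions of the requested entries in the merged grid, input order
  pos <- order(ord)[length(fit$times_h) + seq_along(t_req_h)]
  list(flt = flt, req_rows = pos, t_req_h = t_req_h)
}

#' Predict positions (with uncertainty) at arbitrary times
#'
#' Smoothed CTCRW state at each requested time. The 95% positional
#' error-ellipse semi-major axis is sqrt(5.991 * lambda_max) with
#' lambda_max the largest eigenvalue of the 2x2 position covariance;
#' this is the quantity screened by the 4-km positional-uncertainty
#' rule. Times more than `max_extrapolate_h` beyond the tracked span
#' are flagged (and trigger a warning).
#'
#' @param fit a [fit_ctcrw()] object
#' @param times POSIXct vector
#' @param max_extrapolate_h hours, default 6
#' @return data.frame: time, lon, lat, x, y, var_x, var_y, cov_xy,
#'   ellipse95_semi_major (m), extrapolated (logical)
#' @export
predict_positions <- function(fit, times, max_extrapolate_h = 6) {
  run <- ctcrw_grid_run(fit, times)
  sm <- ctcrw_smooth(run$flt)
  rows <- run$req_rows
  xs <- sm$m_smooth[rows, 1]; ys <- sm$m_smooth[rows, 3]
  var_x <- var_y <- cov_xy <- e95 <- numeric(length(rows))
  for (i in seq_along(rows)) {
    Pp <- sm$P_smooth[[rows[i]]][c(1, 3), c(1, 3)]
    var_x[i] <- Pp[1, 1]; var_y[i] <- Pp[2, 2]; cov_xy[i] <- Pp[1, 2]
    lam <- eigen(Pp, symmetric = TRUE, only.values = TRUE)$values
    e95[i] <- sqrt(CHI2_95_DF2 * max(lam))
  }
  lonlat <- unproject_aeqd(xs, ys, fit$center)
  extrap <- run$t_req_h < min(fit$times_h) - max_extrapolate_h |
    run$t_req_h > max(fit$times_h) + max_extrapolate_h
  if (any(extrap)) {
    warning(sum(extrap), " requested time(s) extrapolate more than ",
            max_extrapolate_h, " h beyond the tracked span", call. = FALSE)
  }
  data.frame(time = parse_utc(times), lon = lonlat[, "lon"],
             lat = lonlat[, "lat"], x = xs, y = ys,
             var_x = var_x, var_y = var_y, cov_xy = cov_xy,
             ellipse95_semi_major = e95, extrapolated = extrap)
}

#' Draw multiple imputations of the track
#'
#' K independent draws from the joint smoothing distribution of the
#' path (forward-filter backward-sampling), evaluated at the requested
#' times. Across-imputation means and variances converge to the
#' smoother's as K grows.
#'
#' @param fit a [fit_ctcrw()] object
#' @param times POSIXct vector at which positions are wanted
#' @param K number of imputations, default 20 (must be >= 2)
#' @param seed integer RNG seed
#' @return object of class "ctcrw_imputations": list with times, K,
#'   seed, and lon / lat / x / y matrices of dim (length(times), K)
#' @export
impute_tracks <- function(fit, times, K = 20, seed = 1) {
  check_that(K >= 2, "K must be at least 2")
  run <- ctcrw_grid_run(fit, times)
  rows <- run$req_rows
  n <- length(rows)
  x <- matrix(NA_real_, n, K); y <- matrix(NA_real_, n, K)
  lon <- matrix(NA_real_, n, K); lat <- matrix(NA_real_, n, K)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  for (k in seq_len(K)) {
    draw <- ctcrw_ffbs_draw(run$flt)
    x[, k] <- draw[rows, 1]; y[, k] <- draw[rows, 3]
    ll <- unproject_aeqd(x[, k], y[, k], fit$center)
    lon[, k] <- ll[, "lon"]; lat[, k] <- ll[, "lat"]
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(list(times = parse_utc(times), K = K, seed = seed,
                 x = x, y = y, lon = lon, lat = lat,
                 animal_id = fit$animal_id),
            class = "ctcrw_imputations")
}

#' @export
print.ctcrw_imputations <- function(x, ...) {
  cat("CTCRW imputation set: K = ", x$K, " paths at ", length(x$times),
      " times (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Reroute on-land (or too-shallow) points to the nearest sea cell
#'
#' Any point whose seafloor depth is shallower than `isobath` (land
#' included) is moved to the nearest grid cell at or beyond the isobath
#' (nearest-sea-cell relocation; path topology is not considered).
#'
#' @param lon,lat point coordinates
#' @param bathy bathymetry [grid_raster()], depth m positive down
#' @param isobath m, default 20
#' @return data.frame: lon, lat (adjusted), moved, displacement_m
#' @export
reroute_land <- function(lon, lat, bathy, isobath = 20) {
  depth <- extract_at(bathy, lon, lat)$value
  offending <- which(is.na(depth) | depth < isobath)
  out <- data.frame(lon = lon, lat = lat, moved = FALSE,
                    displacement_m = 0)
  if (!length(offending)) return(out)
  sea <- which(bathy$values >= isobath, arr.ind = TRUE)
  check_that(nrow(sea) > 0, "no sea cell at or beyond the isobath")
  sea_lon <- bathy$lon[sea[, 1]]; sea_lat <- bathy$lat[sea[, 2]]
  for (i in offending) {
    ## equirectangular distance is adequate for nearest-cell search
    dx <- (sea_lon - lon[i]) * cos(lat[i] * pi / 180)
    dy <- sea_lat - lat[i]
    j <- which.min(dx^2 + dy^2)
    out$lon[i] <- sea_lon[j]; out$lat[i] <- sea_lat[j]
    out$moved[i] <- TRUE
    out$displacement_m[i] <- geosphere::distGeo(c(lon[i], lat[i]),
                                                c(sea_lon[j], sea_lat[j]))
  }
  out
}
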