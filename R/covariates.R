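## Environmental covariate derivation, extraction at dive locations,
## and collinearity screening.

#' Seafloor slope from a bathymetry raster
#'
#' Horn's 3x3 finite-difference gradient with cell sizes scaled to
#' meters (meridional arc for latitude, parallel arc shrunk by
#' cos(latitude) for longitude). Depth sign does not matter: slope is
#' invariant to sign and additive constants. Border cells use replicated
#' edges.
#'
#' @param bathy single-layer [grid_raster()] of seafloor depth (m)
#' @return grid_raster of slope in degrees, [0, 90)
#' @export
slope_from_bathymetry <- function(bathy) {
  z <- bathy$values
  nx <- nrow(z); ny <- ncol(z)
  check_that(nx >= 3 && ny >= 3, "bathymetry grid must be at least 3 x 3")
  ## Pad by edge replication so the output covers the full grid.
  zp <- z[c(1, 1:nx, nx), c(1, 1:ny, ny)]
  m_per_deg <- 111320
  dlon <- abs(mean(diff(bathy$lon)))
  dlat <- abs(mean(diff(bathy$lat)))
  dy_m <- dlat * m_per_deg
  slope <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    dx_m <- dlon * m_per_deg * cos(bathy$lat[j] * pi / 180)
    jj <- j + 1
    z1 <- zp[1:nx, jj - 1]; z2 <- zp[2:(nx + 1), jj - 1]; z3 <- zp[3:(nx + 2), jj - 1]
    z4 <- zp[1:nx, jj];                                   z6 <- zp[3:(nx + 2), jj]
    z7 <- zp[1:nx, jj + 1]; z8 <- zp[2:(nx + 1), jj + 1]; z9 <- zp[3:(nx + 2), jj + 1]
    dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * dx_m)
    dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * dy_m)
    slope[, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  grid_raster(bathy$lon, bathy$lat, slope, name = "slope")
}

#' Derive current magnitude and log10 chlorophyll layers
#'
#' Adds `current_magnitude` = sqrt(u^2 + v^2) cellwise from the zonal
#' (u) and meridional (v) current components, and `chl_log10` =
#' log10(chl) with non-positive chlorophyll mapped to NA.
#'
#' @param env [raster_stack()] with layers u, v, chl
#' @return the stack with the derived layers added
#' @export
derive_fields <- function(env) {
  check_that(all(c("u", "v") %in% names(env$layers)),
             "stack must contain layers 'u' and 'v'")
  env$layers$current_magnitude <- sqrt(env$layers$u^2 + env$layers$v^2)
  if ("chl" %in% names(env$layers)) {
    chl <- env$layers$chl
    chl[!is.na(chl) & chl <= 0] <- NA
    env$layers$chl_log10 <- log10(chl)
  }
  env
}

#' Assemble per-dive environmental and temporal covariates
#'
#' For each dive (time + estimated position), extracts time-of-day
#' (HST), moon phase, seafloor depth and slope, and the daily fields
#' (current magnitude, mixed layer depth, SST, log10 chlorophyll-a and
#' its 30-day lag). Daily layers are matched on the dive's HST calendar
#' date; the lagged chlorophyll value comes from the layer dated exactly
#' `chl_lag_days` earlier. Dives in chlorophyll cells carrying the
#' land-overlap flag get `chl_flagged = TRUE`.
#'
#' @param dives data.frame with columns start (POSIXct UTC), lon, lat
#' @param bathy bathymetry [grid_raster()] (depth m, positive down)
#' @param env environmental [raster_stack()] (after [derive_fields()])
#' @param chl_lag_days default 30
#' @return `dives` with covariate columns appended
#' @export
build_dive_covariates <- function(dives, bathy, env, chl_lag_days = 30) {
  slope <- slope_from_bathymetry(bathy)
  d <- dives
  d$time_of_day <- hst_hour(d$start)
  d$moon_phase <- moon_phase(d$start)
  d$seafloor_depth <- extract_at(bathy, d$lon, d$lat)$value
  d$slope <- extract_at(slope, d$lon, d$lat)$value
  for (nm in c("current_magnitude", "mld", "sst")) {
    if (nm %in% names(env$layers)) {
      d[[nm]] <- extract_at(env, d$lon, d$lat, d$start, nm)$value
    }
  }
  if ("chl_log10" %in% names(env$layers)) {
    now <- extract_at(env, d$lon, d$lat, d$start, "chl_log10")
    lag <- extract_at(env, d$lon, d$lat, d$start, "chl_log10",
                      lag_days = chl_lag_days)
    d$chl_log10 <- now$value
    d$chl_log10_lag30 <- lag$value
    d$chl_flagged <- now$flagged | lag$flagged
  }
  d
}

#' Screen covariates for collinearity
#'
#' Computes pairwise Pearson correlations on complete cases; within any
#' pair with |r| above `threshold`, the lower-priority covariate is
#' dropped (priority order given by `priority`; covariates not listed
#' rank below all listed ones, in their given order). The procedure is
#' greedy on the largest offending |r| and its result does not depend on
#' column order given the priority list. Zero-variance columns are
#' excluded with a warning.
#'
#' @param x data.frame of candidate covariates (numeric columns)
#' @param threshold |Pearson r| above which a pair conflicts, default 0.5
#' @param priority character vector, most-preferred first; default keeps
#'   lagged chlorophyll over contemporaneous chlorophyll and SST
#' @return list with `retained`, `dropped`, and the correlation matrix
#' @export
correlation_screen <- function(x, threshold = 0.5,
                               priority = c("chl_log10_lag30",
                                            "current_magnitude", "mld",
                                            "slope", "chl_log10", "sst")) {
  x <- as.data.frame(x)[vapply(x, is.numeric, logical(1))]
  check_that(ncol(x) >= 2, "need at least two covariates")
  cc <- stats::complete.cases(x)
  check_that(sum(cc) >= 3, "need at least 3 complete rows")
  x <- x[cc, , drop = FALSE]
  zv <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(zv)) {
    warning("excluding zero-variance column(s): ",
            paste(names(x)[zv], collapse = ", "), call. = FALSE)
    x <- x[, !zv, drop = FALSE]
  }
  cm <- stats::cor(x)
  rank_of <- function(nm) {
    r <- match(nm, priority)
    ifelse(is.na(r), length(priority) + match(nm, colnames(cm)), r)
  }
  retained <- colnames(cm)
  dropped <- character(0)
  repeat {
    sub <- cm[retained, retained, drop = FALSE]
    diag(sub) <- 0
    if (max(abs(sub)) <= threshold) break
    idx <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)[1, ]
    pair <- retained[idx]
    loser <- pair[which.max(rank_of(pair))]
    dropped <- c(dropped, loser)
    retained <- setdiff(retained, loser)
    if (length(retained) < 2) break
  }
  list(retained = retained, dropped = dropped, correlations = cm)
}
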