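## Probable near-seafloor dive classification from imputed dive
## positions and bathymetry.

#' Seafloor-depth statistics across track imputations for each dive
#'
#' For every candidate dive (candidates should already be screened to
#' positional-uncertainty <= 4 km), extracts the seafloor depth under
#' each of the K imputed dive positions and summarizes them: sample
#' (n-1) standard deviation, maximum, the depth difference
#' (max seafloor - dive depth), and the ratio of dive depth to the
#' seafloor depth at the smoothed point-estimate position. Imputations
#' falling outside the bathymetry yield NA; a dive with more than
#' `max_nodata_frac` missing imputations is dropped with a warning.
#'
#' @param dives data.frame: dive_id, time, depth (m), and point-estimate
#'   lon, lat (smoothed positions)
#' @param imputations [impute_tracks()] result whose times align with
#'   `dives$time` (row i of the imputation grid is dive i)
#' @param bathy bathymetry [grid_raster()], depth m positive down
#' @param max_nodata_frac default 0.25
#' @return data.frame of class "seafloor_stats": dive_id,
#'   n_imputations, sd_seafloor, max_seafloor, depth_difference, ratio
#' @export
compute_seafloor_stats <- function(dives, imputations, bathy,
                                   max_nodata_frac = 0.25) {
  imp <- imputations
  check_that(nrow(imp$lon) == nrow(dives),
             "imputation grid does not match the dive table")
  K <- imp$K
  n <- nrow(dives)
  sd_sf <- max_sf <- diff_sf <- ratio <- rep(NA_real_, n)
  n_ok <- integer(n)
  point_sf <- extract_at(bathy, dives$lon, dives$lat)$value
  for (i in seq_len(n)) {
    depths <- extract_at(bathy, imp$lon[i, ], imp$lat[i, ])$value
    ok <- !is.na(depths)
    n_ok[i] <- sum(ok)
    if (n_ok[i] < K * (1 - max_nodata_frac)) next
    sd_sf[i] <- stats::sd(depths[ok])
    max_sf[i] <- max(depths[ok])
    diff_sf[i] <- max_sf[i] - dives$depth[i]
    if (!is.na(point_sf[i]) && point_sf[i] > 0) {
      ratio[i] <- dives$depth[i] / point_sf[i]
    }
  }
  dropped <- which(n_ok < K * (1 - max_nodata_frac))
  if (length(dropped)) {
    warning(length(dropped), " dive(s) dropped: > ",
            round(100 * max_nodata_frac), "% of imputed positions ",
            "fall outside the bathymetry", call. = FALSE)
  }
  out <- data.frame(dive_id = dives$dive_id %||% seq_len(n),
                    n_imputations = n_ok, sd_seafloor = sd_sf,
                    max_seafloor = max_sf, depth_difference = diff_sf,
                    ratio = ratio)
  class(out) <- c("seafloor_stats", "data.frame")
  out
}

#' Classify probable near-seafloor dives
#'
#' A dive is a probable near-seafloor dive when the seafloor depths
#' across imputations are consistent (SD <= `sd_max`) and its depth is
#' within `diff_max` of the maximum imputed seafloor depth in either
#' direction (|max seafloor - dive depth| <= diff_max; dives may be
#' somewhat deeper than the maximum seafloor estimate because seafloor
#' depth varies within a grid cell). Tightening either threshold can
#' only remove dives from the probable set.
#'
#' @param stats a [compute_seafloor_stats()] table
#' @param sd_max m, default 100
#' @param diff_max m, default 100
#' @return logical vector, NA where stats are missing
#' @export
classify_near_seafloor <- function(stats, sd_max = 100, diff_max = 100) {
  stats$sd_seafloor <= sd_max & abs(stats$depth_difference) <= diff_max
}

#' Per-animal summary of near-seafloor diving
#'
#' @param dives candidate-dive table with animal_id, depth (m),
#'   duration (s), shape, and a diel `label` column
#' @param probable logical from [classify_near_seafloor()] (same order)
#' @param ratio optional ratio column from the stats table
#' @return data.frame, one row per animal: candidate and probable
#'   counts, percent probable, median and range of depth and duration
#'   (range NA for a single dive), median and minimum ratio, shape and
#'   diel-category counts
#' @export
summarize_near_seafloor <- function(dives, probable, ratio = NULL) {
  out <- list()
  for (id in unique(dives$animal_id)) {
    sel <- dives$animal_id == id
    n_cand <- sum(sel)
    p <- sel & !is.na(probable) & probable
    n_prob <- sum(p)
    row <- data.frame(animal_id = id, n_candidate = n_cand,
                      n_probable = n_prob,
                      pct_probable = if (n_cand > 0) 100 * n_prob / n_cand
                                     else NA_real_)
    if (n_prob == 0) {
      row$median_depth <- NA_real_; row$depth_lo <- NA_real_
      row$depth_hi <- NA_real_; row$median_duration_min <- NA_real_
      row$median_ratio <- NA_real_; row$min_ratio <- NA_real_
      row$n_square <- 0L; row$n_u <- 0L; row$n_v <- 0L
      row$n_dawn <- 0L; row$n_day <- 0L; row$n_dusk <- 0L; row$n_night <- 0L
      row$empty <- TRUE
    } else {
      d <- dives[p, , drop = FALSE]
      row$median_depth <- stats::median(d$depth)
      ## range convention: omitted (NA) for a single dive
      row$depth_lo <- if (n_prob > 1) min(d$depth) else NA_real_
      row$depth_hi <- if (n_prob > 1) max(d$depth) else NA_real_
      row$median_duration_min <- stats::median(d$duration) / 60
      rr <- if (!is.null(ratio)) ratio[p] else rep(NA_real_, n_prob)
      row$median_ratio <- stats::median(rr, na.rm = TRUE)
      row$min_ratio <- if (n_prob > 1) suppressWarnings(min(rr, na.rm = TRUE))
                       else NA_real_
      row$n_square <- sum(d$shape == "square")
      row$n_u <- sum(d$shape == "u")
      row$n_v <- sum(d$shape == "v")
      lab <- if (!is.null(d$label)) d$label else rep(NA_character_, n_prob)
      row$n_dawn <- sum(lab == "dawn", na.rm = TRUE)
      row$n_day <- sum(lab == "day", na.rm = TRUE)
      row$n_dusk <- sum(lab == "dusk", na.rm = TRUE)
      row$n_night <- sum(lab == "night", na.rm = TRUE)
      row$empty <- FALSE
    }
    out[[length(out) + 1]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hexagon-style gridded dive summary
#'
#' Square-cell spatial binning of dives into cells of a given area with
#' per-cell dive count, mean and max depth, and CV of depth; cells with
#' a single dive are excluded from the depth summaries.
#'
#' @param dives data.frame with lon, lat, depth
#' @param cell_area_km2 default 750
#' @return data.frame: cell lon/lat centers, n_dives, mean_depth,
#'   max_depth, cv_depth
#' @export
grid_dive_summary <- function(dives, cell_area_km2 = 750) {
  side_km <- sqrt(cell_area_km2)
  km_per_deg <- 111.32
  lat0 <- mean(dives$lat)
  dlon <- side_km / (km_per_deg * cos(lat0 * pi / 180))
  dlat <- side_km / km_per_deg
  ix <- floor(dives$lon / dlon); iy <- floor(dives$lat / dlat)
  key <- paste(ix, iy)
  out <- lapply(unique(key), function(k) {
    b <- dives[key == k, ]
    if (nrow(b) < 2) return(NULL)
    data.frame(lon = (mean(floor(b$lon / dlon)) + 0.5) * dlon,
               lat = (mean(floor(b$lat / dlat)) + 0.5) * dlat,
               n_dives = nrow(b), mean_depth = mean(b$depth),
               max_depth = max(b$depth),
               cv_depth = 100 * stats::sd(b$depth) / mean(b$depth))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      n_dives = integer(0), mean_depth = numeric(0),
                      max_depth = numeric(0), cv_depth = numeric(0)))
  }
  rownames(res) <- NULL
  res
}
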