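## Time-depth-recorder processing: zero-offset correction, dive
## detection, per-dive statistics, shape classification, time-at-depth.

#' Construct a TDR profile
#'
#' @param time POSIXct UTC at a fixed 1-Hz (or other regular) step
#' @param depth m, positive down
#' @param velocity optional relative swim velocity (uncalibrated units)
#' @param animal_id identifier
#' @return object of class "tdr_profile"
#' @export
tdr_profile <- function(time, depth, velocity = NULL, animal_id = "unknown") {
  time <- parse_utc(time)
  check_that(length(time) == length(depth), "time and depth lengths differ")
  dt <- diff(as.numeric(time))
  check_that(length(dt) == 0 || all(abs(dt - dt[1]) < 1e-6),
             "time must increase at a fixed step")
  structure(list(time = time, depth = as.numeric(depth),
                 velocity = velocity, animal_id = animal_id,
                 dt = if (length(dt)) dt[1] else 1),
            class = "tdr_profile")
}

#' Zero-offset correction of a depth series
#'
#' Pressure transducers drift with temperature, so the recorded "surface"
#' value wanders away from zero. The correction estimates a surface
#' baseline as a low quantile (default 2%) of the depths within
#' consecutive windows (default 30 min), linearly interpolates the
#' baseline to every sample, subtracts it, and clips small negative
#' residuals to zero. This assumes the animal surfaces within every
#' window, which holds for air-breathing divers at these window lengths.
#'
#' @param profile a [tdr_profile()]
#' @param window minutes per baseline window, default 30
#' @param probs quantile treated as the surface, default 0.02
#' @param clip negatives shallower than `clip` m are set to 0 (default 2)
#' @return corrected tdr_profile (with attribute "baseline")
#' @export
zero_offset_correct <- function(profile, window = 30, probs = 0.02, clip = 2) {
  p <- profile
  n <- length(p$depth)
  win_n <- round(window * 60 / p$dt)
  check_that(win_n >= 2, "window must span at least 2 samples")
  idx <- seq_len(n)
  block <- ceiling(idx / win_n)
  centers <- tapply(idx, block, function(i) mean(range(i)))
  base <- tapply(p$depth, block, stats::quantile, probs = probs, names = FALSE)
  baseline <- stats::approx(centers, base, xout = idx, rule = 2)$y
  corrected <- p$depth - baseline
  corrected[corrected < 0 & corrected > -clip] <- 0
  p$depth <- corrected
  attr(p, "baseline") <- baseline
  p
}

#' Detect dives in a corrected TDR profile
#'
#' A dive is a maximal run of samples at or beyond `threshold` meters.
#' Per dive: maximum depth; duration (number of samples times the step);
#' bottom time (time at >= 80% of maximum depth); descent rate (depth
#' gain from the first dive sample to the first bottom sample over the
#' elapsed time); ascent rate (analogous from the last bottom sample to
#' the last dive sample); and shape from the bottom-time fraction of the
#' dive duration: square when > 0.5, u when > 0.2 and <= 0.5, v when
#' <= 0.2. Dives truncated by the record edge are flagged `partial`;
#' dives reaching within 2 m of `sensor_ceiling` are flagged `saturated`
#' (their reported maximum depth is a lower bound).
#'
#' @param profile corrected [tdr_profile()]
#' @param threshold m, default 10
#' @param bottom_frac fraction of max depth defining the bottom phase,
#'   default 0.8
#' @param sensor_ceiling m, sensor saturation depth (default Inf)
#' @return data.frame of dives: start, end, max_depth, duration,
#'   bottom_time, descent_rate, ascent_rate, shape, partial, saturated
#' @export
detect_dives <- function(profile, threshold = 10, bottom_frac = 0.8,
                         sensor_ceiling = Inf) {
  p <- profile
  wet <- p$depth >= threshold
  if (!any(wet)) {
    return(data.frame(start = p$time[0], end = p$time[0], max_depth = numeric(0),
                      duration = numeric(0), bottom_time = numeric(0),
                      descent_rate = numeric(0), ascent_rate = numeric(0),
                      shape = character(0), partial = logical(0),
                      saturated = logical(0)))
  }
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dive_runs <- which(r$values)
  out <- lapply(dive_runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    d <- p$depth[i0:i1]
    maxd <- max(d)
    bottom <- which(d >= bottom_frac * maxd)
    b0 <- min(bottom); b1 <- max(bottom)
    n_bot <- sum(d >= bottom_frac * maxd)
    duration <- length(d) * p$dt
    bottom_time <- n_bot * p$dt
    frac <- bottom_time / duration
    shape <- if (frac > 0.5) "square" else if (frac > 0.2) "u" else "v"
    descent <- if (b0 > 1) (d[b0] - d[1]) / ((b0 - 1) * p$dt) else 0
    ascent <- if (b1 < length(d)) (d[b1] - d[length(d)]) / ((length(d) - b1) * p$dt) else 0
    data.frame(start = p$time[i0], end = p$time[i1], max_depth = maxd,
               duration = duration, bottom_time = bottom_time,
               descent_rate = descent, ascent_rate = ascent, shape = shape,
               partial = (i0 == 1 || i1 == length(p$depth)),
               saturated = maxd >= sensor_ceiling - 2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time-at-depth proportions
#'
#' Fraction of samples in each depth bin. Bin i spans
#' [bin_edges[i], bin_edges[i+1]); the final edge may be Inf. The
#' proportions sum to 1 exactly when the edges cover all depths.
#'
#' @param profile corrected [tdr_profile()]
#' @param bin_edges increasing depth edges in m (first usually 0,
#'   last usually Inf)
#' @return named numeric vector of proportions, one per bin
#' @export
time_at_depth <- function(profile, bin_edges) {
  check_that(!is.unsorted(bin_edges, strictly = TRUE),
             "bin_edges must be strictly increasing")
  d <- profile$depth
  bin <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  bin[bin == 0] <- 1 # depths below the first edge count in the first bin
  bin[bin >= length(bin_edges)] <- length(bin_edges) - 1
  counts <- tabulate(bin, nbins = length(bin_edges) - 1)
  props <- counts / length(d)
  names(props) <- paste0("[", utils::head(bin_edges, -1), ",",
                         utils::tail(bin_edges, -1), ")")
  props
}
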