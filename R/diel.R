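## Solar/lunar geometry, civil diel categories, and interval splitting.

#' Geometric solar elevation angle
#'
#' Computes the sun's elevation above the horizon from standard solar
#' geometry (mean solar coordinates, equation of time, declination and
#' hour angle; the low-accuracy NOAA formulation). No atmospheric
#' refraction is applied; accuracy is about 0.2 degrees, well within the
#' 0.5-degree contract needed for civil diel categorization.
#'
#' @param time POSIXct (UTC) or parseable timestamp vector
#' @param lon,lat position in decimal degrees (east, north positive)
#' @return solar elevation in degrees, vectorized over inputs
#' @export
solar_elevation <- function(time, lon, lat) {
  time <- parse_utc(time)
  n <- max(length(time), length(lon), length(lat))
  time <- rep_len(time, n); lon <- rep_len(lon, n); lat <- rep_len(lat, n)

  ## Julian centuries since J2000.0
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  deg2rad <- pi / 180
  ## Geometric mean longitude and anomaly of the sun (degrees)
  L0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ## Equation of center, true longitude, apparent longitude
  C <- sin(M * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * deg2rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)
  ## Obliquity of the ecliptic (corrected)
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * deg2rad)
  ## Solar declination
  decl <- asin(sin(obliq * deg2rad) * sin(app_long * deg2rad)) / deg2rad
  ## Equation of time (minutes)
  y <- tan(obliq / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (y * sin(2 * L0 * deg2rad) -
    2 * e * sin(M * deg2rad) +
    4 * e * y * sin(M * deg2rad) * cos(2 * L0 * deg2rad) -
    0.5 * y^2 * sin(4 * L0 * deg2rad) -
    1.25 * e^2 * sin(2 * M * deg2rad))
  ## True solar time (minutes) and hour angle (degrees)
  utc_min <- (as.numeric(time) %% 86400) / 60
  tst <- (utc_min + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360

  sin_el <- sin(lat * deg2rad) * sin(decl * deg2rad) +
    cos(lat * deg2rad) * cos(decl * deg2rad) * cos(ha * deg2rad)
  asin(pmin(1, pmax(-1, sin_el))) / deg2rad
}

#' Civil diel category at a time and place
#'
#' Categories follow the civil-twilight convention: day when the sun is
#' more than 6 degrees above the horizon, night when more than 6 degrees
#' below, and dawn or dusk within the plus/minus 6 degree band depending
#' on whether the sun is rising or setting (elevation derivative over a
#' plus/minus 5 minute window).
#'
#' @inheritParams solar_elevation
#' @param band half-width of the twilight band in degrees (default 6)
#' @return character vector in {"dawn","day","dusk","night"}
#' @export
diel_category <- function(time, lon, lat, band = 6) {
  time <- parse_utc(time)
  n <- max(length(time), length(lon), length(lat))
  time <- rep_len(time, n); lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  el <- solar_elevation(time, lon, lat)
  out <- character(n)
  out[el > band] <- "day"
  out[el < -band] <- "night"
  tw <- which(out == "")
  if (length(tw)) {
    rising <- solar_elevation(time[tw] + 300, lon[tw], lat[tw]) >
      solar_elevation(time[tw] - 300, lon[tw], lat[tw])
    out[tw] <- ifelse(rising, "dawn", "dusk")
  }
  out
}

## Reference new moon used as the phase epoch (2000-01-06 18:14 UTC) and
## the mean synodic month in days.
LUNAR_EPOCH_S <- 947182440
SYNODIC_DAYS <- 29.530588853

#' Lunar phase angle
#'
#' Mean synodic lunar phase in radians on [0, 2*pi): 0 at new moon, pi at
#' full moon, advancing monotonically through the synodic month. Phase is
#' computed from elapsed time since a reference new moon at the mean
#' synodic rate; true phase can lead or lag the mean phase by several
#' hours, which is immaterial at the monthly scale modeled here.
#'
#' @param time POSIXct (UTC) or parseable timestamps
#' @return phase angle in radians, [0, 2*pi)
#' @export
moon_phase <- function(time) {
  time <- parse_utc(time)
  frac <- ((as.numeric(time) - LUNAR_EPOCH_S) / (SYNODIC_DAYS * 86400)) %% 1
  frac * 2 * pi
}

#' Split a time interval at diel-category or clock-hour boundaries
#'
#' Partitions [start, end) into sub-intervals that each lie entirely
#' within one civil diel category (mode "diel") or one Hawaiian Standard
#' Time clock hour (mode "clock_hour"). Sub-interval durations sum
#' exactly to the parent duration. Diel boundaries are located by a
#' coarse scan followed by bisection to millisecond precision.
#'
#' @param start,end POSIXct UTC interval endpoints, end > start
#' @param mode "diel" or "clock_hour"
#' @param lon,lat position used for solar geometry (mode "diel")
#' @return data.frame with columns start, end, duration (s), and label
#'   (diel category or integer HST hour)
#' @export
split_interval <- function(start, end, mode = c("diel", "clock_hour"),
                           lon = NULL, lat = NULL) {
  mode <- match.arg(mode)
  start <- parse_utc(start); end <- parse_utc(end)
  check_that(length(start) == 1 && length(end) == 1, "start/end must be scalar")
  check_that(as.numeric(end) > as.numeric(start), "interval duration must be > 0")

  if (mode == "clock_hour") {
    s <- as.numeric(start) + HST_OFFSET_S
    e <- as.numeric(end) + HST_OFFSET_S
    cuts <- seq(ceiling(s / 3600) * 3600, by = 3600,
                length.out = max(0, floor((e - ceiling(s / 3600) * 3600) / 3600) + 1))
    cuts <- cuts[cuts > s & cuts < e]
    bounds <- c(s, cuts, e)
    labels <- (floor(bounds[-length(bounds)] / 3600) %% 24)
    starts <- bounds[-length(bounds)] - HST_OFFSET_S
    ends <- bounds[-1] - HST_OFFSET_S
  } else {
    check_that(!is.null(lon) && !is.null(lat),
               "mode = 'diel' requires lon and lat")
    s <- as.numeric(start); e <- as.numeric(end)
    ## Coarse scan: twilight bands last tens of minutes at these
    ## latitudes, so a 30-s grid cannot step over a category.
    grid <- unique(c(seq(s, e, by = 30), e))
    cat_grid <- diel_category(.POSIXct(grid, tz = "UTC"), lon, lat)
    bounds <- s
    labels <- cat_grid[1]
    for (i in seq_len(length(grid) - 1)) {
      if (cat_grid[i + 1] != cat_grid[i]) {
        lo <- grid[i]; hi <- grid[i + 1]
        ## Bisect the change point to ~1 ms
        while (hi - lo > 1e-3) {
          mid <- (lo + hi) / 2
          if (diel_category(.POSIXct(mid, tz = "UTC"), lon, lat) == cat_grid[i]) {
            lo <- mid
          } else hi <- mid
        }
        bounds <- c(bounds, hi)
        labels <- c(labels, cat_grid[i + 1])
      }
    }
    bounds <- c(bounds, e)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
  }
  data.frame(
    start = .POSIXct(starts, tz = "UTC"),
    end = .POSIXct(ends, tz = "UTC"),
    duration = ends - starts,
    label = labels,
    stringsAsFactors = FALSE
  )
}

#' Split surface records of a behavior log by diel category or clock hour
#'
#' Applies [split_interval()] to every surface record; dive records are
#' never split and are labeled by their start time (dives are short
#' relative to surface periods, and splitting them would break per-dive
#' metrics). Positions for diel labeling are taken from `lon`/`lat`
#' columns when present, else from the supplied deployment coordinates.
#'
#' @param records behavior record data.frame (see [read_behavior_log()])
#' @param mode "diel" or "clock_hour"
#' @param lon,lat fallback coordinates when records carry none
#' @return the records expanded into labeled sub-records, with a `label`
#'   column; sub-record durations of a parent sum to the parent duration
#' @export
split_records <- function(records, mode = c("diel", "clock_hour"),
                          lon = NULL, lat = NULL) {
  mode <- match.arg(mode)
  recs <- records
  out <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    p_lon <- if (!is.null(r$lon) && is.finite(r$lon)) r$lon else lon
    p_lat <- if (!is.null(r$lat) && is.finite(r$lat)) r$lat else lat
    if (identical(r$kind, "dive")) {
      lab <- if (mode == "diel") {
        diel_category(r$start, p_lon, p_lat)
      } else as.integer(floor(hst_hour(r$start)))
      piece <- r
      piece$label <- lab
      out[[i]] <- piece
    } else {
      sp <- split_interval(r$start, r$end, mode, p_lon, p_lat)
      piece <- r[rep(1, nrow(sp)), , drop = FALSE]
      piece$start <- sp$start
      piece$end <- sp$end
      piece$duration <- sp$duration
      piece$label <- sp$label
      out[[i]] <- piece
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
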