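## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse timestamps to POSIXct in UTC
#'
#' Accepts POSIXct (coerced to UTC) or ISO-8601-style character strings.
#' @param x timestamp vector
#' @return POSIXct, tz = "UTC"
#' @keywords internal
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}

## Hawaiian Standard Time is fixed at UTC-10 (no daylight saving).
HST_OFFSET_S <- -10 * 3600

#' Local clock hour in Hawaiian Standard Time
#' @param time POSIXct UTC
#' @return numeric hour of day in [0, 24)
#' @keywords internal
hst_hour <- function(time) {
  secs <- as.numeric(time) + HST_OFFSET_S
  (secs %% 86400) / 3600
}

#' Calendar date in Hawaiian Standard Time
#' @keywords internal
hst_date <- function(time) {
  as.Date(floor((as.numeric(time) + HST_OFFSET_S) / 86400), origin = "1970-01-01")
}

#' Project lon/lat to planar meters (azimuthal equidistant)
#'
#' Azimuthal equidistant projection centered on `center`; x east, y north,
#' in meters. Distances/azimuths on the WGS84 ellipsoid via geosphere.
#' @param lon,lat coordinates in decimal degrees
#' @param center numeric length-2 (lon, lat) projection center
#' @return matrix with columns x, y (meters)
#' @keywords internal
project_aeqd <- function(lon, lat, center) {
  p <- cbind(lon, lat)
  d <- geosphere::distGeo(center, p)
  b <- geosphere::bearing(center, p)
  b <- ifelse(is.na(b), 0, b) # coincident with center
  cbind(x = d * sin(b * pi / 180), y = d * cos(b * pi / 180))
}

#' Inverse of [project_aeqd()]
#' @keywords internal
unproject_aeqd <- function(x, y, center) {
  d <- sqrt(x^2 + y^2)
  b <- atan2(x, y) * 180 / pi
  out <- geosphere::destPoint(center, b, d)
  colnames(out) <- c("lon", "lat")
  out
}

#' Derive a reproducible child seed from a parent seed
#'
#' Deterministic fan-out of one run seed into per-stage / per-animal seeds,
#' kept within the 32-bit integer range.
#' @keywords internal
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629L)
}

#' Stop unless a condition holds
#' @keywords internal
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
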