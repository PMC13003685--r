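## Minimal regular lon/lat gridded-field containers used for bathymetry
## and daily environmental fields, with plain-text (long CSV) I/O.

#' Construct a single-layer lon/lat raster
#'
#' @param lon,lat strictly monotone coordinate vectors (cell centers,
#'   decimal degrees)
#' @param values matrix of dim c(length(lon), length(lat))
#' @param flag optional logical matrix of the same dim (e.g., land flag)
#' @param name layer name
#' @return object of class "grid_raster"
#' @export
grid_raster <- function(lon, lat, values, flag = NULL, name = "layer") {
  check_that(!is.unsorted(lon, strictly = TRUE) ||
               !is.unsorted(rev(lon), strictly = TRUE),
             "lon must be strictly monotone")
  check_that(!is.unsorted(lat, strictly = TRUE) ||
               !is.unsorted(rev(lat), strictly = TRUE),
             "lat must be strictly monotone")
  check_that(is.matrix(values) &&
               all(dim(values) == c(length(lon), length(lat))),
             "values must be a matrix of dim c(length(lon), length(lat))")
  if (!is.null(flag)) {
    check_that(all(dim(flag) == dim(values)), "flag dim must match values")
  }
  structure(list(lon = lon, lat = lat, values = values, flag = flag,
                 name = name), class = "grid_raster")
}

#' Construct a daily stack of lon/lat rasters
#'
#' @param lon,lat coordinate vectors
#' @param dates Date vector, one per time slice
#' @param layers named list of 3-d arrays, each of dim
#'   c(length(lon), length(lat), length(dates))
#' @param flag optional logical matrix (static, e.g., land-overlap flag)
#' @return object of class "raster_stack"
#' @export
raster_stack <- function(lon, lat, dates, layers, flag = NULL) {
  for (nm in names(layers)) {
    check_that(all(dim(layers[[nm]]) == c(length(lon), length(lat), length(dates))),
               paste0("layer '", nm, "' has wrong dimensions"))
  }
  structure(list(lon = lon, lat = lat, dates = as.Date(dates),
                 layers = layers, flag = flag), class = "raster_stack")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("grid_raster '", x$name, "': ", length(x$lon), " x ", length(x$lat),
      " cells, lon [", min(x$lon), ", ", max(x$lon), "], lat [",
      min(x$lat), ", ", max(x$lat), "]\n", sep = "")
  invisible(x)
}

#' @export
print.raster_stack <- function(x, ...) {
  cat("raster_stack: ", paste(names(x$layers), collapse = ", "), "; ",
      length(x$lon), " x ", length(x$lat), " cells x ", length(x$dates),
      " days\n", sep = "")
  invisible(x)
}

nearest_index <- function(coord, x) {
  i <- findInterval(x, (coord[-1] + coord[-length(coord)]) / 2) + 1
  i[x < min(coord) - abs(coord[2] - coord[1]) / 2] <- NA
  i[x > max(coord) + abs(coord[2] - coord[1]) / 2] <- NA
  i
}

#' Extract raster values at points
#'
#' Nearest-cell lookup in space; for a time-varying stack the layer
#' whose date equals the point's HST calendar date (minus `lag_days`) is
#' used. Points outside the grid, or dates outside the stack, yield NA.
#' Nearest-cell (rather than bilinear) lookup is deliberate: tag-derived
#' positions carry kilometer-scale uncertainty, so sub-cell
#' interpolation adds nothing.
#'
#' @param raster a [grid_raster()] or [raster_stack()]
#' @param lon,lat point coordinates (decimal degrees)
#' @param time POSIXct UTC, required for a raster_stack
#' @param layer layer name, required for a raster_stack
#' @param lag_days days to subtract from the HST date before matching a
#'   stack layer (e.g., 30 for a 30-day-lagged field); default 0
#' @return list with `value` and logical `flagged` (flag layer at the
#'   cell, FALSE where no flag layer exists)
#' @export
extract_at <- function(raster, lon, lat, time = NULL, layer = NULL,
                       lag_days = 0) {
  ii <- nearest_index(raster$lon, lon)
  jj <- nearest_index(raster$lat, lat)
  n <- max(length(lon), length(lat))
  value <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  inside <- !is.na(ii) & !is.na(jj)
  if (inherits(raster, "grid_raster")) {
    value[inside] <- raster$values[cbind(ii[inside], jj[inside])]
    if (!is.null(raster$flag)) {
      flagged[inside] <- raster$flag[cbind(ii[inside], jj[inside])]
    }
  } else {
    check_that(!is.null(time) && !is.null(layer),
               "raster_stack extraction needs time and layer")
    dates <- hst_date(parse_utc(time)) - lag_days
    kk <- match(dates, raster$dates)
    ok <- inside & !is.na(kk)
    value[ok] <- raster$layers[[layer]][cbind(ii[ok], jj[ok], kk[ok])]
    if (!is.null(raster$flag)) {
      flagged[ok] <- raster$flag[cbind(ii[ok], jj[ok])]
    }
  }
  list(value = value, flagged = flagged)
}

#' Write / read a raster as a long-format gridded CSV
#'
#' Plain-text interchange: columns lon, lat (and date for stacks), then
#' one column per layer; the flag layer is stored as 0/1.
#' @param raster grid_raster or raster_stack
#' @param file path
#' @export
write_gridded_csv <- function(raster, file) {
  if (inherits(raster, "grid_raster")) {
    df <- expand.grid(lon = raster$lon, lat = raster$lat)
    df[[raster$name]] <- as.vector(raster$values)
    if (!is.null(raster$flag)) df$flag <- as.integer(as.vector(raster$flag))
  } else {
    df <- expand.grid(lon = raster$lon, lat = raster$lat, date = raster$dates)
    for (nm in names(raster$layers)) df[[nm]] <- as.vector(raster$layers[[nm]])
    if (!is.null(raster$flag)) {
      df$flag <- as.integer(rep(as.vector(raster$flag), length(raster$dates)))
    }
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_gridded_csv
#' @param name layer name for single-layer files
#' @export
read_gridded_csv <- function(file, name = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  has_time <- "date" %in% names(df)
  value_cols <- setdiff(names(df), c("lon", "lat", "date", "flag"))
  if (!has_time) {
    nm <- name %||% value_cols[1]
    ord <- order(match(df$lat, lat), match(df$lon, lon))
    vals <- matrix(df[[nm]][ord], nrow = length(lon))
    flag <- if ("flag" %in% names(df)) {
      matrix(df$flag[ord] > 0, nrow = length(lon))
    } else NULL
    grid_raster(lon, lat, vals, flag = flag, name = nm)
  } else {
    dates <- sort(unique(as.Date(df$date)))
    ord <- order(match(as.Date(df$date), dates), match(df$lat, lat),
                 match(df$lon, lon))
    layers <- lapply(value_cols, function(nm) {
      array(df[[nm]][ord], dim = c(length(lon), length(lat), length(dates)))
    })
    names(layers) <- value_cols
    flag <- if ("flag" %in% names(df)) {
      matrix((df$flag[ord] > 0)[seq_len(length(lon) * length(lat))],
             nrow = length(lon))
    } else NULL
    raster_stack(lon, lat, dates, layers, flag = flag)
  }
}
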