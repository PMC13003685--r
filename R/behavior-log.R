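## Reading, quality control, and standardization of satellite-tag
## behavior logs (alternating dive/surface records summarized onboard).

#' Column dialect for behavior-log CSV files
#'
#' Maps the logical fields of a behavior log onto the column names used
#' in a particular file dialect. Defaults follow the Wildlife-Computers
#' style *-Behavior.csv layout.
#'
#' @param what,start,end,duration_min,duration_max,depth_min,depth_max,shape
#'   column names in the file
#' @param animal_id optional column carrying the animal/deployment id
#' @return named list of column names
#' @export
behavior_log_dialect <- function(what = "What", start = "Start", end = "End",
                                 duration_min = "DurationMin",
                                 duration_max = "DurationMax",
                                 depth_min = "DepthMin", depth_max = "DepthMax",
                                 shape = "Shape", animal_id = "DeployID") {
  list(what = what, start = start, end = end,
       duration_min = duration_min, duration_max = duration_max,
       depth_min = depth_min, depth_max = depth_max,
       shape = shape, animal_id = animal_id)
}

#' Read a behavior-log CSV into typed records
#'
#' Parses dive and surface records, computing the working depth and
#' duration of each record as the mean of the reported minimum and
#' maximum estimates. Records are returned sorted by start time; a
#' warning reports how many rows were out of order in the file.
#'
#' @param file path to a behavior-log CSV
#' @param dialect column mapping from [behavior_log_dialect()]
#' @return data.frame of records: animal_id, kind ("dive"/"surface"),
#'   start, end (POSIXct UTC), depth_min, depth_max, dur_min, dur_max,
#'   shape ("square","u","v","none"), depth (m), duration (s)
#' @export
read_behavior_log <- function(file, dialect = behavior_log_dialect()) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  ## auto-detect this package's own normalized output format
  normalized <- !dialect$what %in% names(raw) &&
    all(c("kind", "start", "end", "shape") %in% names(raw))
  if (normalized) {
    dialect <- behavior_log_dialect(what = "kind", start = "start",
                                    end = "end", duration_min = "dur_min",
                                    duration_max = "dur_max",
                                    depth_min = "depth_min",
                                    depth_max = "depth_max",
                                    shape = "shape",
                                    animal_id = "animal_id")
  }
  required <- c("what", "start", "end", "duration_min", "duration_max",
                "depth_min", "depth_max", "shape")
  for (f in required) {
    if (!dialect[[f]] %in% names(raw)) {
      stop("behavior log is missing required column '", dialect[[f]], "'",
           call. = FALSE)
    }
  }
  parse_col <- function(col) {
    x <- raw[[dialect[[col]]]]
    out <- tryCatch(suppressWarnings(parse_utc(x)), error = function(e) NULL)
    if (is.null(out)) {
      ok <- vapply(x, function(v) {
        !inherits(tryCatch(suppressWarnings(parse_utc(v)),
                           error = function(e) e), "error")
      }, logical(1))
      bad <- which(!ok)
      stop("unparseable timestamp in column '", dialect[[col]], "', row ",
           bad[1], ": '", x[bad[1]], "'", call. = FALSE)
    }
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(bad)) {
      stop("unparseable timestamp in column '", dialect[[col]], "', row ",
           bad[1], ": '", x[bad[1]], "'", call. = FALSE)
    }
    out
  }
  start <- parse_col("start")
  end <- parse_col("end")
  kind <- tolower(trimws(raw[[dialect$what]]))
  check_that(all(kind %in% c("dive", "surface")),
             "record type column must contain only 'Dive'/'Surface'")
  shape <- tolower(trimws(as.character(raw[[dialect$shape]])))
  shape[is.na(shape) | !nzchar(shape)] <- "none"
  check_that(all(shape %in% c("square", "u", "v", "none")),
             "dive shape must be one of square/u/v or blank")
  animal <- if (dialect$animal_id %in% names(raw)) {
    as.character(raw[[dialect$animal_id]])
  } else rep("unknown", nrow(raw))

  rec <- data.frame(
    animal_id = animal, kind = kind, start = start, end = end,
    depth_min = as.numeric(raw[[dialect$depth_min]]),
    depth_max = as.numeric(raw[[dialect$depth_max]]),
    dur_min = as.numeric(raw[[dialect$duration_min]]),
    dur_max = as.numeric(raw[[dialect$duration_max]]),
    shape = shape, stringsAsFactors = FALSE
  )
  rec$depth <- (rec$depth_min + rec$depth_max) / 2
  rec$duration <- (rec$dur_min + rec$dur_max) / 2
  ## normalized files carry explicit depth/duration columns (surface
  ## records have no min/max bracket); prefer them where present
  if (normalized) {
    if ("depth" %in% names(raw)) {
      v <- as.numeric(raw$depth)
      rec$depth <- ifelse(is.na(rec$depth), v, rec$depth)
    }
    if ("duration" %in% names(raw)) {
      v <- as.numeric(raw$duration)
      rec$duration <- ifelse(is.na(rec$duration), v, rec$duration)
    }
  }
  ord <- order(rec$animal_id, as.numeric(rec$start))
  n_moved <- sum(ord != seq_along(ord))
  if (n_moved > 0) {
    warning(n_moved, " rows were out of time order and have been sorted",
            call. = FALSE)
    rec <- rec[ord, ]
    rownames(rec) <- NULL
  }
  rec
}

#' Quality-control report for a behavior log
#'
#' Screens a deployment's records for signs of pressure-transducer
#' trouble and structural inconsistencies. Per-record flags:
#' \itemize{
#'  \item implausible_depth: negative minimum depth or maximum depth
#'    beyond `max_plausible_depth`;
#'  \item duration_mismatch: |reported duration - (end - start)| beyond
#'    `tolerance` seconds;
#'  \item overlap: record starts before the previous record ends.
#' }
#' A deployment-level drift flag is raised when the daily minimum of
#' reported dive depths rises quasi-monotonically (a proxy for a
#' drifting surface baseline): at least `drift_days` days of data, a
#' total rise of `drift_min_rise` meters or more, and 80% of
#' day-over-day steps increasing.
#'
#' @param records behavior record data.frame
#' @param max_plausible_depth m, default 3000
#' @param tolerance s, default 60
#' @param drift_min_rise m, default 10
#' @param drift_days minimum days of data for the drift test, default 5
#' @return list with `flags` (per-record logical data.frame),
#'   `drift` (logical), and `verdict` ("pass"/"fail")
#' @export
qc_behavior_log <- function(records, max_plausible_depth = 3000,
                            tolerance = 60, drift_min_rise = 10,
                            drift_days = 5) {
  check_that(nrow(records) > 0, "no records to quality-control")
  r <- records
  is_dive <- r$kind == "dive"
  implausible <- (is_dive & (r$depth_min < 0 | r$depth_max > max_plausible_depth))
  implausible[is.na(implausible)] <- FALSE
  span <- as.numeric(r$end) - as.numeric(r$start)
  mismatch <- abs(r$duration - span) > tolerance
  mismatch[is.na(mismatch)] <- FALSE
  overlap <- rep(FALSE, nrow(r))
  for (id in unique(r$animal_id)) {
    i <- which(r$animal_id == id)
    i <- i[order(as.numeric(r$start[i]))]
    if (length(i) > 1) {
      ov <- as.numeric(r$start[i][-1]) < as.numeric(r$end[i][-length(i)]) - 1e-6
      overlap[i[-1]] <- ov
    }
  }

  ## Drift proxy: trend in the daily minimum of reported dive depths.
  drift <- FALSE
  dives <- r[is_dive & !implausible, ]
  if (nrow(dives) > 0) {
    day <- as.Date(dives$start)
    daily_min <- tapply(dives$depth_min, day, min)
    if (length(daily_min) >= drift_days) {
      steps <- diff(as.numeric(daily_min))
      rise <- as.numeric(daily_min[length(daily_min)]) - as.numeric(daily_min[1])
      if (rise >= drift_min_rise && mean(steps > 0) >= 0.8) drift <- TRUE
    }
  }

  flags <- data.frame(implausible_depth = implausible,
                      duration_mismatch = mismatch,
                      overlap = overlap)
  verdict <- if (any(implausible) || any(overlap) || drift) "fail" else "pass"
  list(flags = flags, drift = drift, verdict = verdict,
       n_flagged = sum(implausible | mismatch | overlap))
}

#' Standardize a behavior log to analysis dive thresholds
#'
#' Reclassifies dive records as surface periods unless they are at least
#' `depth_threshold` meters deep AND at least `duration_threshold`
#' seconds long (tags are programmed with heterogeneous onboard
#' thresholds; this imposes one common definition). Runs of consecutive
#' surface records separated by no more than `gap_tolerance` seconds are
#' merged; larger gaps remain as explicit uncovered time. Total covered
#' duration is conserved exactly: a merged record's duration is the sum
#' of its children's durations.
#'
#' @param records time-sorted, non-overlapping behavior records
#' @param depth_threshold m, default 50
#' @param duration_threshold s, default 120
#' @param gap_tolerance s, micro-gaps absorbed when merging (default 1)
#' @return object of class "standardized_log": list with `records`,
#'   thresholds, and per-animal coverage
#' @export
standardize_log <- function(records, depth_threshold = 50,
                            duration_threshold = 120, gap_tolerance = 1) {
  r <- records
  check_that(nrow(r) > 0, "no records to standardize")
  for (id in unique(r$animal_id)) {
    i <- which(r$animal_id == id)
    i <- i[order(as.numeric(r$start[i]))]
    if (length(i) > 1) {
      ov <- which(as.numeric(r$start[i][-1]) < as.numeric(r$end[i][-length(i)]) - 1e-6)
      if (length(ov)) {
        stop("overlapping records for animal ", id, ": rows ",
             i[ov[1]], " and ", i[ov[1] + 1], call. = FALSE)
      }
    }
  }
  keep_dive <- r$kind == "dive" & r$depth >= depth_threshold &
    r$duration >= duration_threshold
  r$kind <- ifelse(keep_dive, "dive", "surface")
  ## Reclassified dives lose their shape code.
  r$shape[r$kind == "surface"] <- "none"

  out <- list()
  for (id in unique(r$animal_id)) {
    a <- r[r$animal_id == id, ]
    a <- a[order(as.numeric(a$start)), ]
    merged <- list()
    cur <- NULL
    for (j in seq_len(nrow(a))) {
      row <- a[j, ]
      if (identical(row$kind, "surface")) {
        if (!is.null(cur) &&
            as.numeric(row$start) - as.numeric(cur$end) <= gap_tolerance) {
          cur$end <- row$end
          cur$duration <- cur$duration + row$duration
          cur$depth <- NA_real_
          cur$depth_min <- NA_real_; cur$depth_max <- NA_real_
          cur$dur_min <- NA_real_; cur$dur_max <- NA_real_
        } else {
          if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
          cur <- row
        }
      } else {
        if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
        cur <- NULL
        merged[[length(merged) + 1]] <- row
      }
    }
    if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
    out[[id]] <- do.call(rbind, merged)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cov <- vapply(split(res, res$animal_id), function(a) {
    log_coverage(a, min(a$start), max(a$end))
  }, numeric(1))
  structure(list(records = res, depth_threshold = depth_threshold,
                 duration_threshold = duration_threshold, coverage = cov),
            class = "standardized_log")
}

#' @export
print.standardized_log <- function(x, ...) {
  n_dive <- sum(x$records$kind == "dive")
  cat("Standardized behavior log: ", nrow(x$records), " records, ",
      n_dive, " dives (>= ", x$depth_threshold, " m, >= ",
      x$duration_threshold, " s), ",
      length(unique(x$records$animal_id)), " animal(s)\n", sep = "")
  invisible(x)
}

#' Fraction of a time span covered by behavior records
#'
#' Sums record durations clipped to [span_start, span_end] and divides
#' by the span length; gaps in transmission reduce coverage.
#'
#' @param records behavior record data.frame (or standardized_log)
#' @param span_start,span_end POSIXct span over which to assess coverage
#' @return fraction in [0, 1]
#' @export
log_coverage <- function(records, span_start, span_end) {
  if (inherits(records, "standardized_log")) records <- records$records
  s0 <- as.numeric(parse_utc(span_start)); s1 <- as.numeric(parse_utc(span_end))
  check_that(s1 > s0, "span_end must be after span_start")
  a <- pmax(as.numeric(records$start), s0)
  b <- pmin(as.numeric(records$end), s1)
  covered <- sum(pmax(0, b - a))
  min(1, covered / (s1 - s0))
}

#' Write behavior records to a normalized CSV
#'
#' ISO-8601 UTC timestamps; one row per record.
#' @param records behavior record data.frame or standardized_log
#' @param file output path
#' @export
write_behavior_log <- function(records, file) {
  if (inherits(records, "standardized_log")) records <- records$records
  out <- records
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  out$end <- format(out$end, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
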