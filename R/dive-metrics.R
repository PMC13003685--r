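## Dive rates, hour-day modeling units, and median-of-individuals
## group summaries.

#' Dive rate per animal (overall or by diel category)
#'
#' Rate = number of dives divided by the summed duration of dive and
#' surface records (hours), so transmission gaps never enter the
#' denominator. With `grouping = "diel_category"` the records must
#' already carry a `label` column from [split_records()] (surface
#' periods split at category boundaries); each dive counts toward the
#' category of its start.
#'
#' @param records behavior records (a standardized_log or its records),
#'   with a `label` column when grouping by category
#' @param grouping "overall" or "diel_category"
#' @return data.frame: animal_id, group, n_dives, hours, rate
#'   (dives/h); rate is NA (not 0) where a group has no covered time
#' @export
dive_rate <- function(records, grouping = c("overall", "diel_category")) {
  grouping <- match.arg(grouping)
  if (inherits(records, "standardized_log")) records <- records$records
  r <- records
  if (grouping == "overall") {
    r$label <- "overall"
  } else {
    check_that(!is.null(r$label),
               "grouping by diel category needs records split by category")
  }
  out <- list()
  for (id in unique(r$animal_id)) {
    a <- r[r$animal_id == id, ]
    for (g in unique(a$label)) {
      b <- a[a$label == g, ]
      hours <- sum(b$duration) / 3600
      n <- sum(b$kind == "dive")
      out[[length(out) + 1]] <- data.frame(
        animal_id = id, group = g, n_dives = n, hours = hours,
        rate = if (hours > 0) n / hours else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build hour-day modeling units for the hourly dive-rate model
#'
#' One unit per animal x HST date x clock hour, with the number of
#' dives starting in that hour and the covered fraction of the hour
#' (summed record durations). Units covering less than `coverage_min`
#' of the hour are dropped (they would understate the rate); the
#' dropped units are returned too so dives remain fully accounted for.
#'
#' @param records behavior records already split by clock hour
#'   ([split_records()] with mode "clock_hour")
#' @param coverage_min fraction, default 0.75
#' @return list with `units` (retained) and `dropped`; both data.frames
#'   with animal_id, date, hour, n_dives, covered_hours, moon_phase
#' @export
build_hour_units <- function(records, coverage_min = 0.75) {
  r <- records
  check_that(!is.null(r$label), "records must be split by clock hour first")
  r$date <- hst_date(r$start)
  r$hour <- as.integer(r$label)
  key <- paste(r$animal_id, r$date, r$hour)
  units <- list()
  for (k in unique(key)) {
    b <- r[key == k, ]
    covered <- sum(b$duration) / 3600
    mid_hour <- as.POSIXct(paste(b$date[1], "00:00:00"), tz = "UTC") +
      (b$hour[1] + 0.5) * 3600 - HST_OFFSET_S
    units[[length(units) + 1]] <- data.frame(
      animal_id = b$animal_id[1], date = b$date[1], hour = b$hour[1],
      n_dives = sum(b$kind == "dive"),
      covered_hours = min(1, covered),
      moon_phase = moon_phase(mid_hour))
  }
  u <- do.call(rbind, units)
  rownames(u) <- NULL
  keep <- u$covered_hours >= coverage_min
  list(units = u[keep, , drop = FALSE], dropped = u[!keep, , drop = FALSE])
}

#' Median-of-individuals group summary of a dive metric
#'
#' Individual-level medians (or proportions, for dive shapes) are
#' computed first; the group summary is their mean ("grand mean"), SD,
#' and CV in percent across individuals. Dives are never pooled across
#' animals, so no animal dominates by sample size. Single-animal groups
#' report NA (not 0) for SD and CV.
#'
#' @param x per-dive data.frame with animal_id, a metric column, and a
#'   grouping column (or none for overall)
#' @param metric column name to summarize (e.g., "depth", "duration"),
#'   or "shape_proportions" for per-shape proportions
#' @param by optional grouping column name (e.g., a diel label)
#' @return data.frame: group, (shape), grand_mean, sd, cv_percent,
#'   n_individuals
#' @export
group_summary <- function(x, metric, by = NULL) {
  groups <- if (is.null(by)) rep("overall", nrow(x)) else as.character(x[[by]])
  out <- list()
  for (g in unique(groups)) {
    b <- x[groups == g, , drop = FALSE]
    if (identical(metric, "shape_proportions")) {
      shapes <- c("square", "u", "v")
      for (s in shapes) {
        per <- vapply(split(b, b$animal_id),
                      function(a) mean(a$shape == s), numeric(1))
        out[[length(out) + 1]] <- summarize_individuals(g, per, shape = s)
      }
    } else {
      per <- vapply(split(b, b$animal_id),
                    function(a) stats::median(a[[metric]], na.rm = TRUE),
                    numeric(1))
      out[[length(out) + 1]] <- summarize_individuals(g, per)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

summarize_individuals <- function(group, per_animal, shape = NULL) {
  n <- sum(is.finite(per_animal))
  gm <- mean(per_animal, na.rm = TRUE)
  s <- if (n > 1) stats::sd(per_animal, na.rm = TRUE) else NA_real_
  cv <- if (n > 1 && gm != 0) 100 * s / gm else NA_real_
  d <- data.frame(group = group, grand_mean = gm, sd = s,
                  cv_percent = cv, n_individuals = n)
  if (!is.null(shape)) d <- cbind(d[1], shape = shape, d[-1])
  d
}

#' Inter-dive surface durations
#'
#' Time spent in the top of the water column between consecutive dives
#' of an animal. Pairs separated by a data gap longer than
#' `gap_tolerance` minutes are censored (the surface time around a gap
#' is unknown).
#'
#' @param records standardized_log or its records
#' @param gap_tolerance minutes, default 10
#' @return data.frame: animal_id, surface_min (minutes)
#' @export
interdive_surface <- function(records, gap_tolerance = 10) {
  if (inherits(records, "standardized_log")) records <- records$records
  out <- list()
  for (id in unique(records$animal_id)) {
    a <- records[records$animal_id == id, ]
    a <- a[order(as.numeric(a$start)), ]
    di <- which(a$kind == "dive")
    if (length(di) < 2) next
    for (k in seq_len(length(di) - 1)) {
      i0 <- di[k]; i1 <- di[k + 1]
      between <- a[seq(i0 + 1, i1 - 1), , drop = FALSE]
      span <- as.numeric(a$start[i1]) - as.numeric(a$end[i0])
      covered <- sum(between$duration)
      if (span - covered > gap_tolerance * 60) next # censored: gap
      out[[length(out) + 1]] <- data.frame(animal_id = id,
                                           surface_min = span / 60)
    }
  }
  if (!length(out)) {
    return(data.frame(animal_id = character(0), surface_min = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Depth-bin label for a dive
#'
#' Bins are labeled by their upper edge in meters: a 75-m dive falls in
#' bin "100" (dives 50-100 m), a 150-m dive in bin "200" (101-200 m),
#' and so on in 100-m steps.
#' @param depth dive depth in m
#' @param first_upper upper edge of the first bin (default 100)
#' @param width bin width beyond the first (default 100)
#' @return integer upper-edge label
#' @export
depth_bin <- function(depth, first_upper = 100, width = 100) {
  ifelse(depth <= first_upper, first_upper,
         first_upper + width * ceiling((depth - first_upper) / width))
}
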