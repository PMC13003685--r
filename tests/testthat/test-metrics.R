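## A 48-h log with a known per-hour layout: each UTC day, dives start
## on known hours; surface fills the rest; no gaps.
toy_48h_log <- function() {
  t0 <- t_utc("2024-03-01 00:00:00") # 14:00 HST Feb 29
  dive_offsets <- c(3600 * 2 + 600,   # day 1, hour 2 UTC
                    3600 * 2 + 2400,  # day 1, hour 2 UTC (second dive)
                    3600 * 30 + 100,  # day 2, hour 6 UTC
                    3600 * 41 + 1800) # day 2, hour 17 UTC
  dur <- 600
  rows <- list()
  cursor <- 0
  for (off in dive_offsets) {
    rows[[length(rows) + 1]] <- list("surface", cursor, off)
    rows[[length(rows) + 1]] <- list("dive", off, off + dur)
    cursor <- off + dur
  }
  rows[[length(rows) + 1]] <- list("surface", cursor, 48 * 3600)
  rec <- do.call(rbind, lapply(rows, function(r) {
    data.frame(animal_id = "H1", kind = r[[1]], start = t0 + r[[2]],
               end = t0 + r[[3]], depth_min = 198, depth_max = 202,
               dur_min = (r[[3]] - r[[2]]) * 0.99,
               dur_max = (r[[3]] - r[[2]]) * 1.01,
               shape = ifelse(r[[1]] == "dive", "u", "none"),
               depth = ifelse(r[[1]] == "dive", 200, NA),
               duration = r[[3]] - r[[2]], stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  rec
}

test_that("dive rate is dives over covered hours, gaps excluded", {
  ## 12 dives over 24 h of covered records -> 0.5 / h
  t0 <- t_utc("2024-03-01 00:00:00")
  rec12 <- do.call(rbind, lapply(0:11, function(i) {
    s <- t0 + i * 7200
    data.frame(animal_id = "R1", kind = c("dive", "surface"),
               start = c(s, s + 600), end = c(s + 600, s + 7200),
               depth_min = 198, depth_max = 202, dur_min = NA,
               dur_max = NA, shape = c("u", "none"), depth = 200,
               duration = c(600, 6600), stringsAsFactors = FALSE)
  }))
  r <- dive_rate(rec12)
  expect_equal(r$hours, 24)
  expect_equal(r$rate, 0.5)

  rec <- toy_48h_log()
  rate0 <- dive_rate(rec)
  expect_equal(rate0$rate, 4 / 48)
  ## deleting 6 h of surface records shrinks the denominator exactly
  gap <- rec[-nrow(rec), ]
  removed_h <- rec$duration[nrow(rec)] / 3600
  r2 <- dive_rate(gap)
  expect_equal(r2$hours, 48 - removed_h)
  expect_equal(r2$rate, 4 / (48 - removed_h))
})

test_that("per-category rates recombine to the total dive count", {
  scen <- simulate_scenario(scenario_config(n_animals = 2,
                                            duration_days = 4, seed = 41))
  rec <- do.call(rbind, lapply(scen$animals, `[[`, "records"))
  slog <- standardize_log(rec)
  sp <- split_records(slog$records, "diel", lon = scen$center[1],
                      lat = scen$center[2])
  by_cat <- dive_rate(sp, "diel_category")
  total <- dive_rate(slog)
  for (id in unique(by_cat$animal_id)) {
    b <- by_cat[by_cat$animal_id == id, ]
    recombined <- sum(b$rate * b$hours, na.rm = TRUE)
    expect_equal(recombined, total$n_dives[total$animal_id == id],
                 tolerance = 1e-9)
    ## overall rate equals the duration-weighted mean of category rates
    expect_equal(sum(b$rate * b$hours, na.rm = TRUE) / sum(b$hours),
                 total$rate[total$animal_id == id], tolerance = 1e-9)
  }
})

test_that("hour units match hand enumeration on the 48-h toy log", {
  rec <- toy_48h_log()
  sp <- split_records(rec, "clock_hour")
  hu <- build_hour_units(sp)
  expect_equal(nrow(hu$units), 48)
  expect_equal(nrow(hu$dropped), 0)
  expect_equal(sum(hu$units$n_dives), 4)
  ## dives land in their HST start hours: UTC hour - 10 mod 24
  with_dives <- hu$units[hu$units$n_dives > 0, ]
  expect_setequal(
    paste(with_dives$date, with_dives$hour),
    c("2024-02-29 16", "2024-03-01 20", "2024-03-02 7"))
  expect_equal(sum(with_dives$n_dives), 4)
  expect_true(all(abs(hu$units$covered_hours - 1) < 1e-9))
})

test_that("under-covered hours are dropped but dives stay accounted", {
  rec <- toy_48h_log()
  ## delete 40 min out of one dive-free hour (hour 10 UTC of day 1)
  t0 <- rec$start[1]
  cut_s <- as.numeric(t0) + 10 * 3600
  r <- rec
  i <- which(as.numeric(r$start) <= cut_s & as.numeric(r$end) > cut_s)
  pre <- r[seq_len(i - 1), ]
  post <- r[seq(i + 1, nrow(r)), ]
  left <- r[i, ]; right <- r[i, ]
  left$end <- t_utc(format(as.POSIXct(cut_s, tz = "UTC",
                                      origin = "1970-01-01")))
  left$duration <- as.numeric(left$end) - as.numeric(left$start)
  right$start <- as.POSIXct(cut_s + 2400, tz = "UTC",
                            origin = "1970-01-01")
  right$duration <- as.numeric(right$end) - as.numeric(right$start)
  cut_rec <- rbind(pre, left, right, post)
  sp <- split_records(cut_rec, "clock_hour")
  hu <- build_hour_units(sp)
  expect_equal(nrow(hu$dropped), 1)
  expect_equal(hu$dropped$covered_hours, 1 / 3, tolerance = 1e-9)
  ## pooling identity: all dives in retained + dropped units
  expect_equal(sum(hu$units$n_dives) + sum(hu$dropped$n_dives), 4)
})

test_that("group summaries are means of individual medians", {
  x <- data.frame(animal_id = rep(c("A", "B"), each = 5),
                  depth = c(rep(100, 5), rep(300, 5)),
                  shape = rep(c("square", "u", "u", "v", "u"), 2))
  gs <- group_summary(x, "depth")
  expect_equal(gs$grand_mean, 200)
  expect_equal(gs$sd, sd(c(100, 300)))
  expect_equal(gs$cv_percent, 100 * sd(c(100, 300)) / 200)
  expect_equal(gs$n_individuals, 2)
  ## identical animals -> CV 0
  y <- x; y$depth <- 150
  expect_equal(group_summary(y, "depth")$cv_percent, 0)
  ## single-animal group: SD/CV absent, not 0
  z <- x[x$animal_id == "A", ]
  gz <- group_summary(z, "depth")
  expect_true(is.na(gz$sd) && is.na(gz$cv_percent))
  ## median-based: duplicating an animal's rows changes nothing
  dup <- rbind(x, x[x$animal_id == "A", ])
  expect_equal(group_summary(dup, "depth")$grand_mean, 200)
  ## row order irrelevant
  expect_equal(group_summary(x[sample(nrow(x)), ], "depth")$grand_mean,
               200)
  ## shape proportions per animal then averaged
  gp <- group_summary(x, "shape_proportions")
  expect_equal(gp$grand_mean[gp$shape == "u"], 0.6)
  expect_equal(gp$grand_mean[gp$shape == "square"], 0.2)
})

test_that("depth bins are labeled by their upper edge", {
  expect_equal(depth_bin(75), 100)
  expect_equal(depth_bin(100), 100)
  expect_equal(depth_bin(101), 200)
  expect_equal(depth_bin(150), 200)
  expect_equal(depth_bin(999), 1000)
})

test_that("inter-dive surface durations censor across gaps", {
  rec <- toy_48h_log()
  ids <- interdive_surface(rec, gap_tolerance = 10)
  ## three consecutive dive pairs, all gap-free
  expect_equal(nrow(ids), 3)
  expect_equal(ids$surface_min,
               diff(c(3600 * 2 + 600 + 600, 3600 * 2 + 2400,
                      3600 * 30 + 100, 3600 * 41 + 1800))[c(1, 2, 3)] / 60
               - c(0, 600 / 60, 600 / 60),
               tolerance = 1e-9)
  ## delete the surface record between dives 2 and 3 -> censored
  gap <- rec[-5, ]
  expect_equal(nrow(interdive_surface(gap, gap_tolerance = 10)), 2)
})
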