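test_that("reading a behavior log computes mean-of-bracket values", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(toy_behavior_log(), f)
  rec <- read_behavior_log(f)
  expect_equal(nrow(rec), 12)
  d1 <- rec[rec$kind == "dive", ][1, ]
  expect_equal(d1$depth, 100) # mean of (95, 105)
  expect_true(all(rec$shape[rec$kind == "surface"] == "none"))
  expect_s3_class(rec$start, "POSIXct")
  expect_false(is.unsorted(as.numeric(rec$start)))
})

test_that("out-of-order rows are sorted with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy <- toy_behavior_log()
  set.seed(7)
  write_toy_csv(toy[sample(nrow(toy)), ], f)
  expect_warning(rec <- read_behavior_log(f), "out of time order")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(toy, f2)
  expect_equal(rec, read_behavior_log(f2))
})

test_that("missing columns and bad timestamps are reported precisely", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- read.csv(write_toy_csv(toy_behavior_log(), f))
  df$DepthMin <- NULL
  write.csv(df, f, row.names = FALSE)
  expect_error(read_behavior_log(f), "DepthMin")
  df2 <- read.csv(write_toy_csv(toy_behavior_log(), f))
  df2$Start[3] <- "not-a-time"
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_behavior_log(f), "row 3")
})

test_that("quality control flags planted faults and passes clean logs", {
  toy <- toy_behavior_log()
  qc <- qc_behavior_log(toy)
  expect_equal(qc$verdict, "pass")
  expect_equal(qc$n_flagged, 0)

  bad <- toy
  bad$depth_min[2] <- -40
  qc2 <- qc_behavior_log(bad)
  expect_equal(sum(qc2$flags$implausible_depth), 1)
  expect_equal(qc2$verdict, "fail")

  ## +5 m/day ramp over a 10-day log raises the drift flag
  t0 <- t_utc("2024-03-01 00:00:00")
  n_days <- 10
  ramp <- do.call(rbind, lapply(seq_len(n_days * 6) - 1, function(i) {
    day <- i %/% 6
    st <- t0 + i * 14400
    depth <- 100 + 5 * day + (i %% 6)
    data.frame(animal_id = "R1", kind = "dive", start = st,
               end = st + 300, depth_min = depth - 1, depth_max = depth + 1,
               dur_min = 297, dur_max = 303, shape = "u",
               depth = depth, duration = 300)
  }))
  expect_true(qc_behavior_log(ramp)$drift)
  ## the same log without the ramp does not drift
  flat <- ramp
  flat$depth_min <- 99 + rep(0:5, n_days)
  expect_false(qc_behavior_log(flat)$drift)
})

test_that("standardization matches hand enumeration on the toy log", {
  toy <- toy_behavior_log()
  s <- standardize_log(toy)
  r <- s$records
  ## hand enumeration: dives at 100 m/300 s, 60 m/300 s, 50 m/120 s stay;
  ## 49 m, 100 s, and 45 m dives become surface and merge with neighbors
  expect_equal(sum(r$kind == "dive"), 3)
  expect_equal(r$depth[r$kind == "dive"], c(100, 60, 50))
  ## merged runs: records alternate surface/dive strictly
  expect_true(all(r$kind[-1] != r$kind[-nrow(r)]))
  ## total covered duration conserved exactly
  expect_equal(sum(r$duration), sum(toy$duration))
  ## the 45-m dive merged into the following surface block
  i45 <- which(r$kind == "dive" & r$depth == 60) + 1
  expect_equal(as.numeric(r$end[i45]) - as.numeric(r$start[i45]),
               180 + 3120)
})

test_that("both threshold arms reclassify independently", {
  toy <- toy_behavior_log()
  deep_short <- toy[toy$depth == 400 & !is.na(toy$depth), ]
  expect_equal(deep_short$duration, 100) # fails duration arm only
  s <- standardize_log(toy)
  expect_false(400 %in% s$records$depth[s$records$kind == "dive"])
  shallow_long <- toy[toy$depth == 49 & !is.na(toy$depth), ]
  expect_equal(shallow_long$duration, 300) # fails depth arm only
  expect_false(49 %in% s$records$depth[s$records$kind == "dive"])
})

test_that("standardization is idempotent and monotone in thresholds", {
  toy <- toy_behavior_log()
  s1 <- standardize_log(toy)
  s2 <- standardize_log(s1$records)
  expect_equal(s2$records$start, s1$records$start)
  expect_equal(s2$records$kind, s1$records$kind)
  expect_equal(sum(s2$records$duration), sum(s1$records$duration))
  n_dives <- vapply(c(10, 50, 70, 150, 500), function(th) {
    sum(standardize_log(toy, depth_threshold = th)$records$kind == "dive")
  }, numeric(1))
  expect_true(all(diff(n_dives) <= 0))
})

test_that("overlapping records are rejected with the offending pair", {
  toy <- toy_behavior_log()
  toy$end[1] <- toy$end[1] + 120 # overlaps record 2
  expect_error(standardize_log(toy), "overlapping")
})

test_that("coverage is clipped-duration over span", {
  toy <- toy_behavior_log()
  expect_equal(log_coverage(toy, min(toy$start), max(toy$end)), 1.0)
  ## one 6-h record in a 24-h span
  one <- toy[1, ]
  one$end <- one$start + 6 * 3600
  one$duration <- 6 * 3600
  expect_equal(log_coverage(one, one$start, one$start + 86400), 0.25)
})

test_that("generator dropout shows up in coverage", {
  cfg <- scenario_config(n_animals = 1, duration_days = 4,
                         dropout_fraction = 0.3, seed = 5)
  scen <- simulate_scenario(cfg)
  rec <- scen$animals[[1]]$records
  cov <- log_coverage(rec, scen$t0, scen$t0 + 4 * 86400)
  expect_equal(cov, 0.70, tolerance = 0.08)
})

test_that("normalized output CSVs can be read back in", {
  scen <- simulate_scenario(scenario_config(n_animals = 1,
                                            duration_days = 2, seed = 61))
  rec <- scen$animals[[1]]$records
  f <- withr::local_tempfile(fileext = ".csv")
  write_behavior_log(rec, f)
  back <- read_behavior_log(f)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$kind, rec$kind)
  expect_equal(back$depth, rec$depth, tolerance = 1e-9)
  expect_equal(back$duration, rec$duration, tolerance = 1e-6)
  expect_equal(as.numeric(back$start), as.numeric(rec$start),
               tolerance = 1e-3)
  ## the round trip standardizes identically
  s1 <- standardize_log(rec); s2 <- standardize_log(back)
  expect_equal(s1$records$kind, s2$records$kind)
})
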