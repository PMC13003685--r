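## End-to-end orchestration: synthetic scenario (optional) -> QC ->
## standardization -> diel splitting -> dive rates -> CTCRW fits ->
## prediction / imputation -> covariates -> near-seafloor
## classification -> GAMMs, with a manifest for record accounting.

#' Run configuration
#'
#' Collects every analysis threshold (with the conventional defaults),
#' the output directory, the run seed, and stage toggles. The
#' configuration round-trips through YAML unchanged.
#'
#' @param out_dir output directory for stage CSVs and the manifest
#' @param seed run seed; per-stage seeds are derived deterministically
#' @param depth_threshold,duration_threshold standardization thresholds
#'   (50 m, 120 s)
#' @param diel_band civil-twilight half-width, degrees (6)
#' @param coverage_min hour-unit coverage floor (0.75)
#' @param max_ellipse_km positional-uncertainty screen for spatial
#'   analyses, km (4)
#' @param sd_max,diff_max near-seafloor thresholds, m (100, 100)
#' @param n_imputations K track imputations (20)
#' @param cor_threshold collinearity screen on |Pearson r| (0.5)
#' @param k GAMM basis dimension (5)
#' @param scenario a [scenario_config()] for the simulate stage (NULL
#'   to analyze externally supplied files)
#' @param stages character vector of stages to run
#' @return list of class "run_config"
#' @export
run_config <- function(out_dir = tempfile("divetag_run_"), seed = 1,
                       depth_threshold = 50, duration_threshold = 120,
                       diel_band = 6, coverage_min = 0.75,
                       max_ellipse_km = 4, sd_max = 100, diff_max = 100,
                       n_imputations = 20, cor_threshold = 0.5, k = 5,
                       scenario = scenario_config(seed = seed),
                       stages = c("simulate", "standardize", "diel",
                                  "rates", "track", "covariates",
                                  "seafloor", "models")) {
  cfg <- as.list(environment())
  check_that(all(c(cfg$depth_threshold, cfg$duration_threshold,
                   cfg$diel_band, cfg$coverage_min, cfg$max_ellipse_km,
                   cfg$sd_max, cfg$diff_max, cfg$n_imputations,
                   cfg$cor_threshold, cfg$k) > 0),
             "thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()]
#' @param file path
#' @export
write_run_config <- function(config, file) {
  x <- unclass(config)
  x$scenario <- if (!is.null(x$scenario)) {
    s <- unclass(x$scenario)
    s$start_date <- as.character(s$start_date)
    s$env_effect_sizes <- as.list(s$env_effect_sizes)
    s
  }
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  x <- yaml::read_yaml(file)
  if (!is.null(x$scenario)) {
    s <- x$scenario
    s$start_date <- as.Date(s$start_date)
    s$env_effect_sizes <- unlist(s$env_effect_sizes)
    s$domain <- as.numeric(unlist(s$domain))
    x$scenario <- do.call(scenario_config, s)
  }
  do.call(run_config, x[setdiff(names(x), character(0))])
}

#' Run the dive-behavior pipeline end-to-end
#'
#' Executes the configured stages on a synthetic scenario, writing one
#' CSV per stage into the run directory plus a JSON manifest with row
#' counts per stage so that every dive record is accounted for
#' (retained + dropped-with-reason at each step).
#'
#' @param config a [run_config()]
#' @param quiet suppress progress messages
#' @return invisible list with the in-memory stage outputs and the
#'   manifest
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[divetag] ", ...)
  manifest <- list(seed = cfg$seed, stages = list())
  outputs <- list()

  ## --- simulate -----------------------------------------------------
  check_that("simulate" %in% cfg$stages,
             "this pipeline build starts from the simulate stage")
  say("simulate: ", cfg$scenario$n_animals, " animals")
  scen <- simulate_scenario(cfg$scenario)
  records <- do.call(rbind, lapply(scen$animals, `[[`, "records"))
  rownames(records) <- NULL
  truth <- do.call(rbind, lapply(scen$animals, `[[`, "truth"))
  rownames(truth) <- NULL
  write_behavior_log(records, file.path(cfg$out_dir, "behavior_log.csv"))
  utils::write.csv(truth[setdiff(names(truth), "time")],
                   file.path(cfg$out_dir, "truth.csv"), row.names = FALSE)
  manifest$stages$simulate <- list(n_records = nrow(records),
                                   n_truth_dives = nrow(truth))
  outputs$scenario <- scen

  ## --- QC + standardize --------------------------------------------
  qc <- qc_behavior_log(records)
  check_that(qc$verdict == "pass",
             "synthetic behavior log failed quality control")
  slog <- standardize_log(records, cfg$depth_threshold,
                          cfg$duration_threshold)
  write_behavior_log(slog, file.path(cfg$out_dir, "standardized_log.csv"))
  n_dives <- sum(slog$records$kind == "dive")
  manifest$stages$standardize <- list(
    n_records = nrow(slog$records), n_dives = n_dives,
    n_reclassified = sum(records$kind == "dive") - n_dives)
  say("standardize: ", n_dives, " dives >= ", cfg$depth_threshold,
      " m & >= ", cfg$duration_threshold, " s")
  outputs$standardized <- slog

  ## --- diel annotation + splitting ---------------------------------
  split_diel <- split_records(slog$records, "diel",
                              lon = scen$center[1], lat = scen$center[2])
  split_hour <- split_records(slog$records, "clock_hour")
  manifest$stages$diel <- list(n_diel_subrecords = nrow(split_diel),
                               n_hour_subrecords = nrow(split_hour))
  outputs$split_diel <- split_diel

  ## --- dive rates and hour units -----------------------------------
  rates <- dive_rate(split_diel, "diel_category")
  hu <- build_hour_units(split_hour, cfg$coverage_min)
  utils::write.csv(rates, file.path(cfg$out_dir, "dive_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(hu$units[setdiff(names(hu$units), character(0))],
                   file.path(cfg$out_dir, "hour_units.csv"),
                   row.names = FALSE)
  manifest$stages$rates <- list(
    n_hour_units = nrow(hu$units), n_hour_units_dropped = nrow(hu$dropped),
    n_dives_in_units = sum(hu$units$n_dives) + sum(hu$dropped$n_dives))
  say("rates: ", nrow(hu$units), " hour units retained")
  outputs$rates <- rates
  outputs$hour_units <- hu

  ## --- track fitting, prediction, imputation ------------------------
  say("track: CTCRW fits")
  dive_tbl <- slog$records[slog$records$kind == "dive", ]
  dive_tbl$dive_id <- seq_len(nrow(dive_tbl))
  preds <- list(); imps <- list(); fits <- list()
  for (id in names(scen$animals)) {
    a <- scen$animals[[id]]
    obs <- prefilter_locations(a$observations)
    fit <- fit_ctcrw(obs)
    dt <- dive_tbl[dive_tbl$animal_id == id, ]
    if (!nrow(dt)) next
    pr <- predict_positions(fit, dt$start)
    pr$dive_id <- dt$dive_id
    imp <- impute_tracks(fit, dt$start, K = cfg$n_imputations,
                         seed = child_seed(cfg$seed, 400 + match(id, names(scen$animals))))
    fits[[id]] <- fit; preds[[id]] <- pr; imps[[id]] <- imp
  }
  pred <- do.call(rbind, preds)
  dive_tbl <- merge(dive_tbl, pred[c("dive_id", "lon", "lat",
                                     "ellipse95_semi_major")],
                    by = "dive_id", sort = TRUE)
  utils::write.csv(dive_tbl[setdiff(names(dive_tbl), c("start", "end"))],
                   file.path(cfg$out_dir, "dive_positions.csv"),
                   row.names = FALSE)
  manifest$stages$track <- list(
    n_fits = length(fits), n_dives_predicted = nrow(dive_tbl),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    sigma_km = vapply(fits, `[[`, numeric(1), "sigma") / 1000)
  outputs$fits <- fits; outputs$imputations <- imps

  ## --- covariates ----------------------------------------------------
  cov_tbl <- build_dive_covariates(dive_tbl, scen$bathy, scen$env)
  cov_tbl$label <- diel_category(cov_tbl$start, cov_tbl$lon, cov_tbl$lat,
                                 band = cfg$diel_band)
  n_flagged <- sum(cov_tbl$chl_flagged, na.rm = TRUE)
  screen <- correlation_screen(
    cov_tbl[c("slope", "current_magnitude", "mld", "sst",
              "chl_log10", "chl_log10_lag30")],
    threshold = cfg$cor_threshold)
  manifest$stages$covariates <- list(
    n_dives = nrow(cov_tbl), n_chl_flagged = n_flagged,
    retained_covariates = screen$retained,
    dropped_covariates = screen$dropped)
  say("covariates: retained ", paste(screen$retained, collapse = ", "))
  outputs$covariates <- cov_tbl
  outputs$screen <- screen

  ## --- near-seafloor classification ---------------------------------
  cand <- cov_tbl[cov_tbl$ellipse95_semi_major <= cfg$max_ellipse_km * 1000, ]
  stats_list <- list()
  for (id in unique(cand$animal_id)) {
    ci <- cand[cand$animal_id == id, ]
    imp <- imps[[id]]
    sel <- match(ci$dive_id,
                 dive_tbl$dive_id[dive_tbl$animal_id == id])
    imp_sub <- imp
    imp_sub$lon <- imp$lon[sel, , drop = FALSE]
    imp_sub$lat <- imp$lat[sel, , drop = FALSE]
    st <- compute_seafloor_stats(ci, imp_sub, scen$bathy)
    st$animal_id <- id
    stats_list[[id]] <- cbind(st, ci[c("depth", "duration", "shape",
                                       "label")])
  }
  sf_stats <- do.call(rbind, stats_list)
  rownames(sf_stats) <- NULL
  probable <- classify_near_seafloor(sf_stats, cfg$sd_max, cfg$diff_max)
  sf_stats$probable <- probable
  sf_sum <- summarize_near_seafloor(sf_stats, probable,
                                    ratio = sf_stats$ratio)
  utils::write.csv(sf_stats, file.path(cfg$out_dir, "seafloor_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(sf_sum, file.path(cfg$out_dir, "seafloor_summary.csv"),
                   row.names = FALSE)
  manifest$stages$seafloor <- list(
    n_candidates = nrow(sf_stats),
    n_probable = sum(probable, na.rm = TRUE),
    n_excluded_ellipse = nrow(cov_tbl) - nrow(cand))
  say("seafloor: ", sum(probable, na.rm = TRUE), " probable of ",
      nrow(sf_stats), " candidates")
  outputs$seafloor <- sf_stats
  outputs$seafloor_summary <- sf_sum

  ## --- GAMMs ----------------------------------------------------------
  if ("models" %in% cfg$stages) {
    say("models: depth / duration / hourly-rate GAMMs")
    env_terms <- intersect(screen$retained,
                           c("slope", "current_magnitude", "mld",
                             "chl_log10_lag30"))
    model_data <- cov_tbl[!cov_tbl$chl_flagged &
                            cov_tbl$ellipse95_semi_major <=
                              cfg$max_ellipse_km * 1000, ]
    spec_depth <- model_spec("depth", "gamma_log", smooth = env_terms,
                             k = cfg$k, random = "factor_smooth")
    spec_dur <- model_spec("duration", "gamma_log", smooth = env_terms,
                           k = cfg$k, random = "factor_smooth")
    fit_depth <- fit_metric_model(model_data, spec_depth)
    fit_dur <- fit_metric_model(model_data, spec_dur)
    hu_units <- hu$units
    hu_units$time_of_day <- hu_units$hour + 0.5
    spec_rate <- model_spec("n_dives", "negbin_log", k = cfg$k,
                            random = "factor_smooth",
                            offset = "covered_hours")
    fit_rate <- fit_metric_model(hu_units, spec_rate)
    for (nm in c("depth", "duration")) {
      f <- if (nm == "depth") fit_depth else fit_dur
      eff <- predict_effects(f, "time_of_day",
                             grid = seq(0, 24, length.out = 49))
      utils::write.csv(eff, file.path(cfg$out_dir,
                                      paste0("effect_", nm, "_tod.csv")),
                       row.names = FALSE)
    }
    manifest$stages$models <- list(
      depth_deviance = fit_depth$deviance_explained,
      duration_deviance = fit_dur$deviance_explained,
      rate_deviance = fit_rate$deviance_explained,
      n_model_dives = nrow(model_data))
    outputs$models <- list(depth = fit_depth, duration = fit_dur,
                           rate = fit_rate)
  }

  manifest$versions <- list(divetag = as.character(utils::packageVersion("divetag")),
                            r = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs$manifest <- manifest
  invisible(outputs)
}
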