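# divetag

Analysis of marine-predator diving behavior from two kinds of
bio-logging tags: depth-transmitting satellite tags ("behavior logs" of
alternating dive/surface records with Argos/GPS locations) and archival
time-depth recorders (1-Hz depth series). The package was built around
the analysis needs of deep-diving odontocete studies — standardizing
heterogeneous tag programming into one dive definition, attributing dive
effort to diel categories, estimating where dives happened despite
kilometer-scale location error, asking whether dives reached the
seafloor, and modeling dive metrics against temporal and oceanographic
covariates — but every threshold is configuration.

## What it computes

* **Behavior-log standardization** — records become dives only if
  ≥ 50 m deep *and* ≥ 2 min long (configurable); sub-threshold dives are
  reclassified as surface time and merged, conserving covered time
  exactly. QC flags transducer drift, implausible depths, and record
  overlaps.
* **TDR processing** — windowed-quantile zero-offset correction, dive
  detection at a 10-m threshold, per-dive statistics (bottom time at
  ≥ 80% of maximum depth; square/u/v shapes at the > 50% / > 20% / ≤ 20%
  bottom-fraction cut-points; descent/ascent rates), and time-at-depth
  distributions.
* **Diel and lunar annotation** — geometric solar elevation (NOAA
  algorithm), civil diel categories (±6°), mean-synodic moon phase, and
  exact splitting of surface records at diel/clock-hour boundaries so
  dive rates use gap-free denominators.
* **Movement modeling** — a continuous-time correlated random walk
  (integrated Ornstein–Uhlenbeck velocity) fit by maximum likelihood
  with a Kalman filter; observation noise from per-record 95% error
  ellipses. Smoothed dive positions with 95%-ellipse uncertainty,
  K-fold track imputation by forward-filter backward-sampling, a
  speed/turn-angle prefilter, and nearest-sea-cell rerouting of on-land
  points.
* **Near-seafloor classification** — seafloor depths under the K
  imputed positions of each dive (positional uncertainty ≤ 4 km);
  probable near-seafloor dives have seafloor-depth SD ≤ 100 m and
  |max seafloor − dive depth| ≤ 100 m.
* **Dive metrics** — gap-aware dive rates (overall, per diel category,
  per clock hour with a 75% coverage rule) and group summaries as means
  of individual medians with SD and CV.
* **GAMMs** — Gamma log-link models of dive depth and duration and a
  negative-binomial log-link model of hourly dive count with a
  log-hours offset; cyclic cubic splines for time-of-day and moon
  phase, shrinkage thin-plate splines for environmental covariates
  (k = 5, REML), random intercepts vs per-animal factor smooths
  compared by conditional AIC, and conditional effect curves for a
  "typical" individual.
* **Synthetic studies** — a generator that simulates tracks, degraded
  locations, behavior logs with planted diel/lunar/environmental
  effects and planted near-seafloor dives, island-slope bathymetry, and
  daily environmental fields, with full ground truth for validation.

## Worked example

```r
library(divetag)

## a small synthetic study: 2 animals, 6 days, known ground truth
scen <- simulate_scenario(scenario_config(n_animals = 2,
                                          duration_days = 6, seed = 42))
rec  <- do.call(rbind, lapply(scen$animals, `[[`, "records"))
slog <- standardize_log(rec)
slog
#> Standardized behavior log: 274 records, 136 dives (>= 50 m, >= 120 s), 2 animal(s)

## grand mean (mean of individual medians) of dive depth
dives <- slog$records[slog$records$kind == "dive", ]
group_summary(dives, "depth")
#>     group grand_mean       sd cv_percent n_individuals
#> 1 overall   262.5823 4.226086   1.609433             2

## dive rates per diel category (surface records split at boundaries)
sp <- split_records(slog$records, "diel",
                    lon = scen$center[1], lat = scen$center[2])
head(dive_rate(sp, "diel_category"), 4)
#>   animal_id group n_dives     hours      rate
#> 1     SYN01   day      42 58.825589 0.7139750
#> 2     SYN01  dusk       3  5.695385 0.5267423
#> 3     SYN01 night      26 73.813948 0.3522370
#> 4     SYN01  dawn       3  5.665078 0.5295602

## movement model for one animal (true beta = 1 /h, sigma = 3 km/h^1.5)
obs <- prefilter_locations(scen$animals[[1]]$observations)
fit <- fit_ctcrw(obs)
fit
#> CTCRW fit: beta = 0.9248 /h, sigma = 2.901 km/h^1.5, loglik = -1482.5, n = 80 locations
```

The standardized log keeps 136 of the emitted dive records as analysis
dives; the two animals' median dive depths average 262.6 m (the
generator plants a 200-m midwater baseline, deepened by mid-day diel and
covariate effects plus planted seafloor dives); dive rates are highest
in daylight, as planted; and the fitted movement parameters recover the
generating values within ~8%.

`run_pipeline(run_config(seed = 1))` chains all stages — simulate, QC,
standardize, diel splitting, rates, track fitting, imputation,
covariate extraction, near-seafloor classification, GAMMs — writing one
CSV per stage and a JSON manifest whose row counts account for every
record at every stage. A thin command-line wrapper with subcommands
(`run-all`, `simulate`, `standardize`, `rates`) is installed at
`inst/cli/divetag.R`.

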