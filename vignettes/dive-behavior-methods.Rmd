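---
title: "Methods: models and design choices in divetag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in divetag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`divetag` is an analysis pipeline for the diving behavior of satellite-
and archival-tagged marine predators. It covers two data streams:

* **Behavior logs** from depth-transmitting satellite tags: alternating
  dive and surface records summarized onboard (start/end time, minimum
  and maximum estimates of depth and duration, and a dive-shape code),
  accompanied by Argos/GPS locations with error ellipses.
* **TDR profiles** from archival time-depth recorders: a 1-Hz depth
  series without geolocation.

Downstream of ingestion the pipeline annotates records with solar and
lunar geometry, computes dive rates on gap-aware denominators, fits a
continuous-time movement model to estimate dive positions with
uncertainty, classifies probable near-seafloor dives against
bathymetry, extracts environmental covariates, and fits penalized-smooth
regressions (GAMMs) of dive depth, dive duration, and hourly dive rate.
A synthetic-data generator produces complete studies with known ground
truth; every stage of the pipeline is validated against that truth.

# Behavior-log standardization

Tags are programmed with heterogeneous onboard depth/duration
thresholds, so raw logs from different deployments are not comparable.
`standardize_log()` imposes one common dive definition: a record is kept
as a dive if and only if its depth is at least 50 m **and** its duration
at least 2 min (both configurable); everything else is reclassified as
surface time. The working depth and duration of each record are the
means of the reported minimum/maximum estimates (the sensor's stated
accuracy is a symmetric ±1%, so the mean of the bracket is the natural
point estimate).

Two bookkeeping rules matter for everything downstream:

* Runs of consecutive surface records separated by ≤ 1 s are merged;
  the merged record's *duration* is the sum of its children's durations,
  so total covered time is conserved exactly. Gaps longer than 1 s stay
  as explicit uncovered time — they are transmission dropouts, not
  surface behavior.
* Standardization is idempotent and monotone in its thresholds: raising
  the depth threshold can only reduce the dive count.

Quality control (`qc_behavior_log()`) flags implausible depths,
duration/interval mismatches, overlapping records, and a deployment-level
pressure-transducer drift proxy (a quasi-monotone rise in the daily
minimum of reported dive depths: ≥ 10 m total rise with 80% of
day-over-day steps increasing, over ≥ 5 days). The drift rule is a
documented stand-in: vendor QC protocols are not algorithmically public,
so the proxy targets the symptom that matters for dive-depth analyses.

# TDR processing

Zero-offset correction removes temperature-induced drift in the surface
reading: the baseline is the 2% quantile of depths within consecutive
30-min windows, linearly interpolated to 1 Hz and subtracted; small
negative residuals (−2 to 0 m) are clipped to zero. This assumes the
animal surfaces within every window — true for air-breathing divers at
these window lengths.

Dives are maximal runs of samples at or beyond 10 m (about two body
lengths for the study species). Per dive, in sample-count convention
(each 1-s sample contributes 1 s):

* *bottom time* = time at ≥ 80% of maximum depth;
* *shape* from the bottom-time fraction of dive duration: square
  (> 0.5), u (> 0.2 and ≤ 0.5), v (≤ 0.2). Boundary values therefore
  resolve to u at exactly 0.5 and v at exactly 0.2, matching the strict
  inequalities of the onboard definitions;
* descent rate = depth gain from the first dive sample to the first
  bottom sample over the elapsed time; ascent analogous. These endpoint
  conventions are documented because vendor software leaves them
  unspecified; tests pin them with analytic triangle and trapezoid
  profiles.
* dives reaching within 2 m of a configured sensor ceiling are flagged
  `saturated` — their maximum depth is a lower bound and they should be
  excluded from depth (but not duration) summaries.

No hysteresis is applied at the 10-m threshold; with 1–2 m sensor
accuracy and a 10-m threshold, surface noise does not approach the
detection boundary.

# Solar and lunar geometry

Solar elevation uses the standard low-accuracy NOAA solar-position
algorithm (declination, equation of time, hour angle), good to ~0.2°,
well within the ±0.5° needed for civil diel categories: day above +6°,
night below −6°, dawn/dusk inside the band depending on the elevation
derivative over ±5 min. At Hawaiian latitudes the sun crosses the 12°
band in roughly an hour, so dawn and dusk are each single contiguous
blocks.

Lunar phase is the mean synodic phase: 2π · (elapsed time since the
reference new moon of 2000-01-06 18:14 UTC) / 29.530588853 d, wrapped to
[0, 2π). True phase leads or lags the mean by up to several hours over a
month; at the monthly scale of the lunar covariate this is immaterial,
and the mean phase is exactly periodic — a property the tests rely on.

Surface records spanning several diel categories (or clock hours) are
split at the boundaries so that dive-rate denominators are attributed to
the right category; boundaries are located by a 30-s coarse scan plus
bisection to 1 ms, and child durations sum exactly to the parent.
Dives are never split: they are short relative to surface periods and
are assigned to the category of their start time (configurable in
principle to midpoint; start time is the default because the hourly
dive-count model also bins dives by start).

All timestamps are UTC internally; Hawaiian Standard Time (fixed UTC−10,
no daylight saving) enters only for clock-hour and calendar-date
covariates.

# The movement model

Locations are modeled with a continuous-time correlated random walk:
per axis, velocity is an Ornstein–Uhlenbeck process
(dv = −β v dt + σ dW) and position its integral. The exact
discretization over a step Δ has velocity autocorrelation e^{−βΔ} and
closed-form process covariance; observation noise comes from each
record's error ellipse, interpreted as a **95% ellipse**: the semi-axes
are scaled by 1/√5.991 to standard deviations and rotated by the
orientation (degrees clockwise from north). GPS records without
ellipses default to a circular 50-m 95% ellipse; semi-axes are floored
at 10 m.

The likelihood is computed by a 4-state Kalman filter (position and
velocity per axis) and maximized over (log β, log σ) with Nelder–Mead
from three dispersed starts. The state prior at the first time centers
on the first observed position with a 100-km positional standard
deviation and the stationary velocity variance σ²/(2β). Tests verify
the filter against an independent brute-force joint-Gaussian likelihood
(the full covariance of the stacked observation vector, built from the
model's moment recursions) to 10⁻⁶ on small instances, and verify 95%
prediction-ellipse coverage of the true position empirically.

Positions at dive times come from the Rauch–Tung–Striebel smoother;
their 2×2 covariance yields the 95%-ellipse semi-major axis
√(5.991 λ_max), the quantity screened by the 4-km positional-uncertainty
rule (strictly-greater exclusion). The 4-km rule is applied to the
semi-major axis because it is the conservative (largest) extent of the
uncertainty region. Multiple imputation draws whole paths from the joint
smoothing distribution by forward-filter backward-sampling; K = 20
imputations by default. A prefilter removes speed violations (> 7.5 m/s
sustained between fixes) and out-and-back spikes before fitting, and a
nearest-sea-cell rule relocates on-land positions beyond the 20-m
isobath (path-topology-aware rerouting is out of scope by design).

# Near-seafloor classification

For each candidate dive (positional uncertainty ≤ 4 km), the seafloor
depth under each of the K imputed positions is extracted
(nearest cell). A dive is a *probable near-seafloor dive* when

* the sample (n−1) standard deviation of the K seafloor depths is
  ≤ 100 m (the position is consistent enough for the comparison to mean
  anything), and
* |max seafloor depth − dive depth| ≤ 100 m, read symmetrically so a
  dive may be up to 100 m deeper than the maximum seafloor estimate —
  seafloor depth varies within a grid cell and around steep features.

The ratio of dive depth to the seafloor depth at the smoothed point
estimate is reported as a water-column-fraction diagnostic. Both
thresholds, K, and the 4-km screen are configuration values; the
classifier is monotone in both thresholds, and in the zero-location-error
limit it reduces exactly to the depth-difference rule.

# Dive metrics

Dive rate is the number of dives divided by the summed duration of dive
and surface records — never wall-clock time — so transmission gaps
cannot deflate rates. Per-category rates use category-split surface
records, and the identity
Σ(category rate × category hours) = total dives holds to rounding.

The hourly dive-rate model's unit of observation is the animal × HST
date × clock hour, with the number of dives *starting* in that hour and
the covered fraction of the hour; units covered < 75% are dropped
(their observed counts would understate the rate), and dropped units
are retained in the output so every dive stays accounted for.

Group summaries are **means of individual medians** (or of individual
shape proportions), with SD and CV (%) across animals; dives are never
pooled across animals, so no individual dominates by sample size, and a
single-animal group reports absent (not zero) SD/CV. Inter-dive surface
durations are censored when a data gap longer than 10 min intervenes.
Depth-bin labels follow the upper-edge convention (a 75-m dive is in bin
"100", a 150-m dive in bin "200").

# GAMMs

Three models, fitted with mgcv by REML:

* dive depth ~ Gamma(log); dive duration ~ Gamma(log);
* hourly dive count ~ negative binomial(log) with an offset of
  log(covered hours), which makes the linear predictor a log *rate*;
  doubling the offset doubles the expected count exactly.

Cyclic covariates (time-of-day, period 24 h; moon phase, period 2π) use
cyclic cubic regression splines with knots pinned to the full period, so
value and first derivative match across the boundary. Other covariates
use thin-plate splines. Basis dimension is k = 5 throughout — these are
smooth, low-frequency ecological signals, and small k keeps the curves
interpretable. Shrinkage term selection uses the shrinkage thin-plate
basis (`bs = "ts"`) plus mgcv's double penalty (`select = TRUE`), so a
covariate without signal collapses to ~0 effective degrees of freedom.

Individual variation enters as either (1) a random intercept per animal
(`bs = "re"`), or (2) a factor smooth (`bs = "fs"`, cyclic marginal) of
time-of-day by animal: each animal gets its own deviation curve with a
shared smoothing parameter. The two structures are compared by AIC on
the fitted gam objects — mgcv's conditional AIC with the penalized-edf
correction of Wood, Pya & Säfken (2016) — together with the difference
in percent deviance explained. Factor smooths are only offered on
time-of-day: all animals experience the full diel cycle, which is not
true of the environmental covariates.

Collinear covariates are screened before fitting: within any pair with
|Pearson r| > 0.5 on complete cases, the lower-priority member is
dropped, with lagged chlorophyll-a outranking contemporaneous
chlorophyll-a and SST (the lag integrates production history and avoids
same-day confounding with the response). |r| is used because the rule
is about shared information, not sign.

Conditional effect curves hold all other covariates at their training
means and exclude the animal-level terms — the functional relationship
for a "typical" individual — with 95% intervals from the coefficient
covariance on the link scale. A k-index (basis-dimension adequacy
check) is reported with each fit; no automatic refit is attempted.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is validated.

* **Movement**: stationary-velocity CTCRW per animal (β = 1 /h,
  σ = 3 km/h^1.5 ⇒ typical speeds ~2 km/h, matching coastal delphinid
  scales), simulated exactly at 1-min resolution on a planar azimuthal
  equidistant frame and inverse-projected to lon/lat. Animals start on
  a ring offshore of the central island and are confined to the study
  domain by reflection at 85% of the half-width — a crude home-range
  emulation that touches few tracks at the default scales.
* **Locations**: Poisson-thinned observation times (12/day), Gaussian
  error with a random anisotropic covariance (major-axis SD lognormal
  around 800 m — Argos-grade), reported as 95% ellipses in exactly the
  convention the fitter assumes. Mahalanobis² of the planted errors is
  χ²(2) by construction, which the tests check.
* **Behavior log**: dive starts from an inhomogeneous Poisson process
  (mean 0.45 dives/h, ±50% sinusoidal diel modulation peaking at
  mid-day HST). Log dive depth = log(200 m) + 0.3·cos(2π(hour−12)/24)
  + 0.1·cos(moon phase) + covariate effects + N(0, 0.5²); durations
  couple to depth through a Gaussian copula with Spearman ρ = 0.7
  (median ~5.5 min). A planted fraction (15%) of dives terminates
  within Uniform(0, 50) m above the seafloor; all other dives keep at
  least 300 m of clearance, so the planted classes are separable by
  ≥ 300 m and classifier sensitivity/specificity against truth is well
  defined. Submergences below the per-tag onboard thresholds (30 m /
  60 s) are emitted as surface periods, emulating onboard truncation;
  reported min/max fields bracket truth by ±1% so the mean-of-bracket
  recovers it exactly. An optional dropout process deletes contiguous
  record blocks to emulate partial transmission coverage (off by
  default).
* **Rasters**: bathymetry is a smooth island-slope surface (tanh ramp
  to 2500 m over ~60 km, a shallow bank, gentle undulation), with land
  where depth = 0 and a land flag on the chlorophyll field. Daily
  environmental fields (chl-a lognormal around 0.08 mg/m³, SST ~25 °C,
  mixed layer depth ~40 m, currents ~±0.25 m/s) are smooth random
  cosine fields evolving as AR(1) in time. Environmental effect sizes
  on log depth default to −0.3 per log₁₀ unit of 30-day-lagged
  chlorophyll, +0.5 per m/s of current magnitude, and +0.005 per m of
  mixed layer depth — signs chosen to emulate shallower diving under
  productive surface water and deeper diving in strong currents and
  deep mixed layers.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: Argos duty cycling and message
corruption, depth quantization of onboard bins (synthetic depths are
continuous), tag attachment effects, non-stationary movement (behavioral
states, area-restricted search), mesoscale oceanographic structure
beyond smooth random fields, and any real bathymetric product's error
characteristics.

# Numerical choices and problem sizes

* Shape-fraction ties: exactly 0.5 → u, exactly 0.2 → v.
* Standardization merges micro-gaps ≤ 1 s; larger gaps stay uncovered.
* Raster extraction is nearest-cell; dive positions carry km-scale
  uncertainty, so bilinear interpolation would add only false precision.
* Seafloor-depth spread across imputations uses the sample (n−1) SD.
* Diel boundaries: 30-s scan + bisection to 1 ms; brute-force 1-s scans
  in the tests agree to within 2 s per boundary.
* CTCRW optimization: Nelder–Mead on (log β, log σ), three dispersed
  starts, relative tolerance 10⁻¹⁰; error-ellipse semi-axes floored at
  10 m.
* Monte-Carlo test sizes were chosen to make the checks sharp but
  cheap: 10,000-step autocorrelation and Rayleigh checks, 20-replicate
  parameter recovery at ~500 locations each, 1,000-time ellipse
  coverage, K = 200 imputation convergence, 20-replicate GAMM shrinkage
  and structure-selection checks at 600–2,000 dives, and a default
  synthetic study of 8 animals × 10 days run end-to-end twice for the
  determinism audit.

# Known limitations

* The lunar covariate is mean-synodic phase, not illuminated fraction
  or true ecliptic longitude.
* The CTCRW has a single behavioral state; σ and β are shared across a
  deployment.
* Rerouting is nearest-sea-cell and can place consecutive points on
  opposite sides of a peninsula; topology-aware rerouting is out of
  scope.
* The near-seafloor classifier inherits the bathymetry's cell size: in
  very steep terrain the ±100-m window misses genuine seafloor dives
  (the planted-truth sensitivity in the default study is ~0.9, not 1).
* Per-covariate deviance partitioning is not implemented; the reported
  surfaces are total deviance explained and per-term effective degrees
  of freedom.
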