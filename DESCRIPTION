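Package: divetag
Title: Dive Behavior Analysis from Satellite Tags and Time-Depth Recorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes and models cetacean diving behavior recorded by
    depth-transmitting satellite tags and archival time-depth recorders.
    Reads and standardizes behavior-log dive/surface records, applies
    zero-offset correction and dive detection to 1-Hz depth series,
    annotates records with solar and lunar geometry, fits continuous-time
    correlated random walk movement models by Kalman filtering with
    multiple track imputation, classifies probable near-seafloor dives
    against bathymetry, extracts environmental covariates, computes dive
    rates and grouped summaries, and fits penalized-smooth (GAMM)
    regressions of dive depth, duration, and hourly dive rate. Includes a
    synthetic-data generator that simulates complete tag deployments with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
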