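Package: batforage
Title: Colony-Level Central-Place Foraging Analysis from GPS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Movement-ecology pipeline for nightly central-place foraging
    trips of cave-roosting bats tracked by GPS. Provides Movebank-dialect
    track ingestion with metric projection, speed and over-water outlier
    filtering, downsampling and regularization to a fixed time grid,
    two-state hidden Markov segmentation of step lengths (gamma) and
    turning angles (wrapped Cauchy) into foraging and commuting,
    straightness indices, foraging-location extraction, on/off-island
    foraging-time models, landscape-constrained null-track simulation,
    hierarchical Bayesian inference on foraging distance and bearing with
    individual random effects (normal and von Mises likelihoods, adaptive
    MCMC), and utilization maps with 95% highest-density contours and
    pairwise colony overlap percentages. A synthetic-data generator
    produces landscapes and bat-nights with known ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
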