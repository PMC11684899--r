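Package: moadjust
Title: Overestimation-Adjusted Multi-Objective Wrapper Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-stage multi-objective optimization wrapper for biomarker
    panel selection in high-dimensional omics data. A first cross-validated
    stage runs a genetic algorithm per fold and learns, by regression on
    meta-features of the candidate solutions (inner-CV fitness, its bootstrap
    standard deviation, and feature-set size), how much each objective's
    fitness is systematically overestimated; a second stage re-runs the
    optimizer with objectives corrected by the predicted overestimation.
    Includes exact hypervolume computation with partial derivatives for up to
    four objectives, the cross-hypervolume, and two set-level estimation-error
    metrics (multi-objective performance error and Pareto delta), plus a
    synthetic omics-like data generator with known informative features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
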