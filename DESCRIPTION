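Package: tremorsense
Title: Parkinsonian Tremor Severity Estimation from Wrist and Ankle Gyroscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Task-independent estimation of UPDRS-III tremor subscores (total,
    resting and action tremor) from triaxial gyroscope recordings made at the
    wrist and ankle during free body movements. Implements band-pass FIR
    preprocessing, segmentation into five-second windows, a registry of 78
    tremor-representative spectral, autocorrelation and cross-axis features,
    two regression back-ends (per-window gradient tree boosting with
    round-level averaging, and a many-to-one stacked LSTM sequence regressor
    trained by backpropagation through time), subject-disjoint evaluation
    protocols (held-out and leave-one-subject-out) with hyperparameter search,
    medication-response and stratified analyses, and a synthetic cohort
    generator that emulates the statistical structure of free-living
    recordings of Parkinson disease patients so that the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
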