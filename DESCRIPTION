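Package: stoprf
Title: Regression Random Forests with Dispersion-Based Stopping Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Regression random forests whose tree expansion can be halted by
    five alternative stopping rules: a minimum parent-node size (Breiman's
    classical nodesize), a minimum leaf-node size, and three node-dispersion
    thresholds that stop splitting once the outcome variance, range, or
    intercentile range within a node falls below a chosen proportion of the
    corresponding statistic in the full training set.  Includes weighted mean
    square prediction error, tenfold cross-validation, threshold-tuning sweeps
    with minimum-MSPE summaries, percentage-excess comparisons across rules,
    and synthetic benchmark generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    randomForest,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
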