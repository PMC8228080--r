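Package: roimkl
Title: ROI-Level Multiple Kernel Learning for Task fMRI Group Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discriminates two subject groups (e.g., children with
    developmental dyslexia versus typical readers) from region-of-interest
    summaries of task fMRI contrast maps. Implements an lp-norm (group-lasso)
    multiple kernel learning support vector machine with one linear kernel per
    cortical region, nested leave-one-pair-out cross-validation with grid
    search, permutation testing, greedy backward region elimination,
    transformation of discriminative weights into forward (activation-pattern)
    weights, and the surrounding stages: synthetic cohort and BOLD simulation,
    outlier-volume quality control, first-level GLM with canonical
    double-gamma HRF, atlas-based region mean extraction, confound
    residualization, and univariate post hoc statistics with Bonferroni
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
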