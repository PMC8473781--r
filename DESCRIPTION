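Package: dfcstates
Title: Dynamic Functional Connectivity State Analysis for ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sliding-window dynamic functional connectivity (DFC)
    analysis of regional fMRI time series: tapered windowed connectivity with an
    optional L1-penalised precision (graphical lasso) estimator, identification
    of recurring connectivity states by k-means clustering under correlation
    distance with exemplar pre-selection and elbow-based model-order choice,
    per-subject state metrics (reoccurrence times, transition frequencies),
    group statistics and clinical correlations with Bonferroni handling, and a
    Lagrangian support vector machine classifier evaluated by nested
    cross-validation with permutation testing. Includes a Markov-switching
    multivariate Gaussian cohort simulator that plants known states, group
    occupancy differences and clinical couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
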