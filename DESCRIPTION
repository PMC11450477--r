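Package: symnet
Title: Regularized Partial-Correlation Networks for Psychosomatic Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation and robustness analysis of regularized partial-correlation
    networks for ordinal questionnaire data on somatic and psychological symptoms.
    Provides questionnaire ingestion and screening (GAD-7, PHQ-2, somatic symptom
    inventories), Spearman-based item selection, graphical-lasso network estimation
    with extended-BIC model selection, expected influence, bridge expected influence
    and nodewise predictability, nonparametric and case-dropping bootstrap machinery
    (edge-weight confidence intervals, correlation-stability coefficients, pairwise
    difference tests), and a latent-Gaussian generator of ordinal data with known
    sparse two-community network structure for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
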