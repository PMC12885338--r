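Package: panelnet
Title: Longitudinal Symptom Network Analysis with Cross-Sectional and
    Cross-Lagged Panel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates regularized partial-correlation networks (Gaussian
    graphical models selected by the extended Bayesian information criterion)
    and cross-lagged panel networks (node-wise LASSO with lambda.1se
    selection) from multi-wave symptom panel data, together with the
    downstream toolkit such analyses require: weighted centrality indices
    (strength, expected influence, closeness, betweenness, in-/out-expected
    influence), permutation tests of network and global-strength invariance
    between waves, nonparametric bootstrap edge confidence intervals and
    difference tests, case-dropping correlation-stability (CS) coefficients,
    and a multiple-imputation sensitivity harness. A synthetic panel
    generator with known contemporaneous and lagged structure provides
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
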