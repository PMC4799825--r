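Package: dialrisk
Title: Intradialytic Malaise Risk Prediction for Hemodialysis Telemonitoring
Version: 0.1.0
Authors@R:
    person("Dialrisk", "Developers", email = "maintainers@dialrisk.dev",
           role = c("aut", "cre"))
Description: A two-stage computer-aided alerting pipeline for home
    hemodialysis telemonitoring. Generates synthetic dialysis-session
    cohorts with a realistic vital-sign correlation structure, computes
    engineered risk features (interdialytic weight gain and a piecewise
    systolic-pressure critical indicator), balances the rare symptomatic
    class by correlated-Gaussian-noise oversampling, trains two Random
    Forest classifiers (one hour and three hours into a session) under
    leave-one-out cross-validation with score fusion, and evaluates them
    with ROC/AUC, Hanley-McNeil standard errors and Youden-index cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
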