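Package: crcindex
Title: Truncated Concordance Index for Prognostic Models with Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrimination measures for prognostic models of the absolute
    risk of an event in the presence of competing risks. Implements the
    truncated cause-specific concordance index with a naive (Harrell-type)
    estimator and inverse-probability-of-censoring-weighted (IPCW) estimators
    under marginal Kaplan-Meier or Cox working models for the censoring
    distribution, influence-function-based asymptotic standard errors under
    independent censoring, percentile bootstrap confidence intervals,
    time-dependent AUC companions, and a cause-specific-hazards simulation
    engine with censoring-rate calibration for bias/RMSE/coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
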