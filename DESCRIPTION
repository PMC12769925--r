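Package: trialcea
Title: Bayesian Cost-Effectiveness Analysis of Trial Resource-Use and Utility Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian models for trial-based economic evaluations at three
    levels of aggregation: total costs and QALYs; per-time costs and utilities;
    and per-time, per-service health care resource use (HRU) with hurdle
    components for structural zeros. Missing outcomes are treated as unknowns
    within MCMC under a missing-at-random assumption, and the ad hoc
    zero-imputation strategies commonly applied to partially observed
    resource-use questionnaires are provided as explicit comparators. Includes
    a synthetic trial generator with known ground truth, QALY and costing
    derivations, MCMC diagnostics (split R-hat, effective sample size), WAIC,
    posterior predictive checks, and the downstream cost-effectiveness layer
    (ICER, cost-effectiveness plane, acceptability curves).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
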