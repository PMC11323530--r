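Package: swhte
Title: Power and Sample Size for Treatment-Effect Heterogeneity in
    Stepped-Wedge Cluster Randomized Trials with Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-stage power calculation and sample-size determination for
    detecting a treatment-by-covariate interaction (heterogeneity of treatment
    effect) in cross-sectional stepped-wedge cluster randomized trials with a
    binary outcome. The variance of the GEE interaction estimator under a
    marginal logistic model is approximated with the model-based (naive)
    formula and with the Kauermann-Carroll and Mancl-DeRouen bias-corrected
    sandwich forms, under simple or nested exchangeable working correlation.
    Includes a Gaussian-copula simulator for correlated binary outcomes with
    specified marginal means and intracluster correlation, a Fisher-scoring
    GEE fitter with naive, robust and bias-corrected empirical standard
    errors, and a replication harness that estimates empirical type I error
    and simulated power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
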