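Package: melsbb
Title: Mixed-Effects Location-Scale Beta-Binomial Models for Bounded
    Longitudinal Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits hierarchical beta-binomial models in which both the average
    success probability (location, logit scale) and the dispersion of the
    underlying beta distribution (scale, log scale) carry fixed effects and
    correlated person-level random effects.  Designed for bounded discrete
    outcomes measured repeatedly in longitudinal panels, such as word-recall
    test scores in ageing cohorts, where floor and ceiling effects bias
    Gaussian estimates of intraindividual variability.  Provides restricted
    cubic spline bases, within/between decomposition of time-varying
    covariates, a synthetic-cohort generator with known truth for parameter
    recovery studies, Laplace-approximate and MCMC inference, Pareto-smoothed
    importance-sampling leave-one-out (PSIS-LOO) model comparison, and
    reporting utilities (odds-ratio and log-dispersion effect tables, age
    prediction curves, predicted score distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    TMB,
    Matrix,
    stats,
    utils
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    rjags,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
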