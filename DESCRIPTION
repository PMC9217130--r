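Package: painrl
Title: Asymmetric Reinforcement-Learning Models of Pain-Avoidance Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and hierarchical Bayesian estimation of delta-rule
    Q-learning models for two-option instrumental pain-avoidance tasks.
    Implements single- and dual-learning-rate variants (separate learning
    rates for received and avoided pain) with softmax choice, group-level
    priors with inverse-probit constraining transforms, adaptive
    Metropolis-within-Gibbs sampling with split-Rhat diagnostics, WAIC
    model comparison on the deviance scale, posterior contrasts between
    treatment groups (highest density intervals, difference distributions),
    model-independent behavioral metrics (outcome-conditioned switch rates,
    lagged outcome-to-switch logistic regression), parameter-recovery
    pipelines, and export of trial-wise expected-pain-probability
    regressors for downstream neuroimaging analyses.
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
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
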