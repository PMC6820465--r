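Package: rlddm
Title: Reinforcement Learning Diffusion Decision Models for Value-Based
    Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling choices and response times in reward-based
    learning experiments with a multi-armed bandit design. Implements
    delta-rule value learning combined with the diffusion decision model
    (RLDDM), in which learned value differences drive the trialwise drift
    rate and mean learned values can modulate the decision threshold.
    Provides the full model space of reinforcement-learning soft-max
    models, static diffusion models, RLDDM variants with linear or
    sigmoidal value-to-drift mappings, and power-decay threshold variants;
    a task generator with representative payoff sampling and constrained
    pair schedules; forward simulation; hierarchical Bayesian estimation
    with convergence diagnostics; WAIC model comparison; posterior
    predictive checks; hierarchical behavioral regressions; and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
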