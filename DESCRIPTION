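Package: iblt
Title: Simulation and Analysis of Volatility-Structured Win/Loss Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the Information Bias Learning Task (IBLT), a two-armed
    probabilistic choice task with independent win and loss outcomes whose
    volatility is manipulated across blocks. Provides a generator of
    volatility-structured task schedules, a synthetic-cohort simulator driven
    by a valence-specific Rescorla-Wagner delta rule with softmax choice, a
    grid-based full-joint-posterior Bayesian fitter for the model parameters
    with AIC/BIC model comparison, the model-free win-/loss-driven choice
    statistic, and a mixed repeated-measures ANOVA layer with generalized
    eta-squared effect sizes for testing training and stimulation effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
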