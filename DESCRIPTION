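Package: looplearn
Title: Computational Modeling of Self-Belief Formation and Revision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses two-session adaptive-feedback
    belief-learning experiments in which participants rate their expected
    performance and receive percentile feedback engineered around their own
    trailing beliefs. Provides the task engine with contingency reversal, a
    nine-model space of Rescorla-Wagner delta-rule learners with
    valence-, ability-, session- and congruency-specific learning rates and
    an extreme-feedback discounting weight, per-participant Bayesian
    estimation by adaptive MCMC (with a fast MAP/Laplace alternative),
    Pareto-smoothed importance-sampling leave-one-out cross-validation,
    random-effects Bayesian model selection with protected exceedance
    probabilities and the Bayesian omnibus risk, valence-bias scores, and a
    synthetic-cohort generator with configurable population effects for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
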