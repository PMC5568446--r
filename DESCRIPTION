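Package: rlbias
Title: Asymmetric Q-Learning Models of Factual and Counterfactual
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, fitting and comparison of Rescorla-Wagner
    Q-learning models with valence- and information-type-asymmetric
    learning rates on a probabilistic two-armed bandit task with partial
    or complete (counterfactual) feedback.  Provides the task generator
    (Symmetric, Asymmetric and Reversal reward contingencies over two
    sessions of 96 trials), a six-model family (Full, Information,
    Valence, Confirmation, Perseveration, One), maximum-likelihood and
    maximum a posteriori estimation with multi-restart bounded
    optimisation, BIC-based random-effects Bayesian model selection with
    exceedance probabilities, parameter-recovery diagnostics, and the
    behavioural indices (preferred choice rate, reversal accuracy,
    normalised learning-rate bias) used to characterise confirmation
    biases in instrumental learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
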