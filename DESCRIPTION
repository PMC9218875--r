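Package: creditseq
Title: Choice-Selective Sequences and Reinforcement-Learning Circuit Models
    for a Probabilistic Reversal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how choice-selective
    sequential population activity in cortical inputs to the nucleus accumbens
    can support trial-by-trial reinforcement learning. Provides a simulator
    for the 70/10 probabilistic reversal lever-press task, a generator of
    synthetic single-trial choice-selective sequences (cortical-like,
    thalamic-like and onset-only variants), a biologically grounded
    temporal-difference learning circuit with dopaminergic reward prediction
    errors and synaptic eligibility traces, an actor-critic recurrent
    (LSTM) network trained with advantage actor-critic, spline-basis
    event-kernel encoding models with circular-shift permutation tests,
    sequence-type-weighted logistic decoders with piecewise trial time
    warping, choice- and outcome-history regressions, and Bayesian
    ideal-observer versus Q-learning comparisons of reward prediction
    errors at block reversals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    splines
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
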