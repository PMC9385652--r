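Package: navrl
Title: Reinforcement Learning Models of Human Spatial Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits and compares reinforcement learning accounts of human
    wayfinding in a room-grid navigation task. Provides the task model (a
    grid of rooms with Fixed and Random goal-seeking phases), five choice
    models (TD(0), TD(1), TD(lambda) with eligibility traces, model-based
    values from dynamic programming, and a weighted hybrid), softmax
    choice likelihoods, bounded maximum-likelihood fitting with restarts,
    BIC model comparison, a seeded synthetic-cohort generator with a known
    omega-theta correlation structure, and the downstream statistics
    (excessive distance, repeated-measures ANOVA, paired t, dependent
    correlation comparison, sensitivity power analysis, parameter and
    model recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
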