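Package: rewarddyn
Title: Group-Level Encoding and Decoding of Anticipatory Reward
    Representations in Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group-level multivariate analysis of trial-structured
    neural time series during reward anticipation. Implements per-time-bin
    encoding MANOVA (F-transformed Pillai-Bartlett trace) and decoding ANOVA
    on group-concatenated data with subject intercepts, per-channel causal
    classification (direct, indirect, brain-state context), cluster-level
    permutation correction over time bins, cross-prediction temporal-stability
    analysis, AIC comparison of reward-variability metrics (coefficient of
    variation, standard deviation, variance), and exponential-utility
    estimation of risk sensitivity from certainty equivalents. A synthetic
    multi-subject data generator with planted ground truth emulates the
    counterbalanced 3 x 3 factorial design (mean reward by coefficient of
    variation) that the statistics assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
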