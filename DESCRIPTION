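Package: adhereda
Title: Adherence Prediction for Cognitive Training with Domain-Adversarial
    Transfer Across Participants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts day-ahead adherence to tablet-based cognitive training
    from daily play logs.  Provides a synthetic cohort generator with
    archetypal playing patterns, FFT-based sliding-window selection, Gramian
    angular field (GAF) imaging of daily play-time series, GAF-feature
    clustering of participants, per-participant 1D convolutional classifiers,
    and a domain-adversarial extension (gradient reversal) that borrows
    training windows from same-cluster participants.  Includes the three-arm
    experimental protocol (target-only, pooled sources, adversarial
    adaptation), confusion-matrix metrics, exact sign test and
    repeated-measures ANOVA for arm comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    utils,
    yaml,
    png,
    readr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
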