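Package: dyadcrqa
Title: Categorical Cross-Recurrence Analysis of Dyadic Movement Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the movement dynamics of two interacting
    people from pose-estimation exports. Reads DeepLabCut-style coordinate
    tables, converts head trajectories into inter-person spatial distance and
    categorical movement direction series (left / right / no movement), and
    quantifies coupling with categorical cross-recurrence quantification
    analysis: diagonal lag profiles with shuffled surrogate baselines,
    recurrence rate, mean diagonal line, vertical and horizontal trapping
    times, and block-area categorical entropy. Lag profiles are summarised as
    density distributions (kurtosis, skewness, dispersion, peak lag) and
    compared between groups with blockwise rank-based tests. A seeded
    generator of coupled leader-follower dyads with known ground truth
    supports validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
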