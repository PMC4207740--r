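Package: chronosleep
Title: Sleep-EEG Quantification, Circadian Activity Profiles and
    Day/Night Expression Screens for Mouse Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying sleep architecture and EEG spectral
    features from epoch-scored mouse polysomnography: vigilance-state time
    budgets and light-dark amplitudes from hypnograms, slow-wave activity
    (0.5-4 Hz NREM delta power) with individual baseline normalization,
    theta peak frequency of REM sleep, sleep-deprivation rebound analysis,
    running-wheel activity profiles, a day/night differential-expression
    screen with fold-change and adjusted-p cut-offs, seed-gene shortest-path
    subnetwork construction with hypergeometric term enrichment, and the
    accompanying test statistics (two-way ANOVA with Bonferroni post-hoc
    tests, Mann-Whitney U). A seeded synthetic-cohort generator (Markov-chain
    hypnograms with diurnal sleep-propensity modulation, a two-process
    homeostat, state-conditional EEG/EMG synthesis, Poisson wheel counts,
    planted rhythmic transcripts) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    Rcpp,
    generics,
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
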