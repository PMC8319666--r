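Package: quiescr
Title: Behavioral State Segmentation and Screen Analysis for Worm Satiety
    Quiescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies roaming, dwelling and quiescence in single-worm
    locomotion recordings. Provides centroid extraction from image stacks,
    speed-series construction, a three-state hidden Markov model over log
    speeds (Baum-Welch fitting, Viterbi decoding, forward-backward
    posteriors), per-animal percent-time and transition-rate estimation,
    bout statistics, and concurrent-control-normalized RNAi screen
    analysis with Bonferroni correction. Includes a synthetic-data
    generator with known ground truth (Markov state sequences, centroid
    tracks, rendered frames, whole mock screens) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
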