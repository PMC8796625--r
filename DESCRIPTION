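Package: moseqr
Title: Ensemble Motion Sequencing of Mouse Behavior and EEG Fast-Ripple
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of mouse pose-feature time series into
    behavioral syllables with an autoregressive hidden Markov model (ARHMM),
    fitted as an ensemble of independent expectation-maximization runs whose
    per-frame state assignments are merged into consensus syllables by WPGMA
    clustering of frame signatures. Provides per-animal syllable statistics
    (frequency, mean bout length, time proportion), nonparametric genotype
    comparison (Kruskal-Wallis with Dunn pairwise z-tests), and syllable
    transition networks. A companion arm detects fast ripples (200-550 Hz
    high-frequency oscillations) in epicranial EEG with an order-2 Butterworth
    band-pass and an amplitude-over-baseline criterion, and summarizes
    per-electrode event rates. Includes generators for switching-AR pose
    sessions and synthetic EEG with injected oscillation bursts, providing
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
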