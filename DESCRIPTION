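Package: dwellclust
Title: Cross-Correlation Clustering of Ion-Channel Dwell-Time Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects repeated, cross-correlated dwell-time sequences in
    single ion-channel patch-clamp records and groups them into clusters
    that act as a phase-space fingerprint of the channel's conformational
    substates. Provides amplitude-threshold idealization of current
    traces, product-sorted greedy template clustering of N-element
    open/closed dwell-time sequences with consistency refinement,
    selection of the correlation threshold by mono- versus bi-exponential
    fits of per-cluster dwell-time distributions, phase-space summaries
    and plots, and an aggregated-Markov gating simulator that supplies
    synthetic validation data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
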