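Package: ersim
Title: Encoding-Retrieval Similarity Analysis for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies hippocampal pattern completion from single-channel
    intracranial EEG recordings of associative-memory experiments.
    Implements dual-regime sliding-window spectral estimation (Hanning
    taper at low frequencies, Slepian multitapers at high frequencies),
    trial-wise encoding-by-retrieval Spearman reinstatement maps with
    association-matched surrogate controls, cluster-based permutation
    inference with minimum-t conjunctions, gamma/alpha power analyses
    linking oscillatory dynamics to reinstatement, and a synthetic local
    field potential simulator with 1/f background, planted time-frequency
    fingerprints and ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
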