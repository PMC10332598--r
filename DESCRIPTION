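Package: vocclust
Title: Unsupervised Clustering of Animal Vocal Repertoires from
    Auto-Encoder Spectrogram Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterise animal vocal repertoires from detected
    vocalisations without supervision. Audio units are extracted around
    annotation centres, turned into fixed-size (k 2^n x k 2^n) Mel or linear
    spectrograms with configurable dynamic-range compression, and embedded
    with a convolutional auto-encoder trained under a pixel or perceptual
    reconstruction loss. Embeddings are projected with UMAP and clustered
    with HDBSCAN; agreement with expert labels is quantified by normalised
    mutual information, repertoire discreteness by the Hopkins statistic,
    and annotation effort by a discriminant-cluster report. A synthetic
    repertoire generator (harmonic stacks with controlled contours, jitter
    and SNR) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and umap-learn on PATH,
    used for the UMAP projection stage (and scikit-learn for the test
    suite's HDBSCAN cross-check).
Config/testthat/edition: 3
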