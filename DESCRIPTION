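Package: entropica
Title: Multiscale Entropy, Complexity and Phase-Based Connectivity for
    Multichannel EEG
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterising the irregularity and functional
    organisation of multichannel neural time series. Implements ordinal-pattern
    symbolisation with permutation entropy and its amplitude-weighted variant,
    Jensen-Shannon statistical complexity and the entropy-complexity plane
    across coarse-grained time scales, Lempel-Ziv complexity under median and
    ordinal symbolisations, weighted phase lag index connectivity networks with
    phase-randomised surrogate thresholding, geodesic entropy of binarised
    networks, cluster-corrected sign-flip permutation statistics with paired
    effect sizes, and leave-one-subject-out linear discriminant decoding.
    Includes a synthetic-data generator that produces two-condition
    multi-subject EEG-like experiments with known injected irregularity and
    lagged-coupling effects, so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
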