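Package: phideid
Title: Privacy-Preserving Collaborative Training of a Clinical PHI Tagger
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects protected health information (PHI) in clinical free text
    with a character-enhanced bidirectional LSTM token tagger, and trains it
    under four regimes: centralized stochastic gradient descent, round-robin
    (cyclic weight transfer), distributed selective stochastic gradient
    descent (DSSGD) through a parameter server that exchanges thresholded,
    clamped, subsampled weight updates, and isolated per-site training.
    Includes a seeded generator of annotated pseudo-clinical corpora so the
    full experimental comparison runs at desk scale without access-restricted
    data, plus token-level binary PHI scoring and learning-curve utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
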