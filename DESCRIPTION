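Package: incfrnn
Title: Incremental Fuzzy-Rough Nearest Neighbour Classification for EEG
    Brainprint Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instance-based incremental learning for EEG-based person
    authentication. Implements the fuzzy-rough nearest neighbour (FRNN)
    classifier with three incremental update strategies for the training
    pool (probability-based, actual-class, and a FIFO-windowed k-nearest
    neighbour baseline), an EEG "distraction descriptor" feature set
    (band-limited power spectral density shape features, wavelet phase
    stability, and magnitude-squared coherence), correlation-based
    feature selection (CFS), a streaming evaluation protocol with
    inverse ten-fold splits and imbalance-aware metrics, and a synthetic
    EEG generator that emulates the statistical structure the method
    assumes (subject-specific alpha peaks, stimulus phase locking,
    inter-channel coupling, artefact trials, and slow drift).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
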