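Package: hdsemgsel
Title: Channel Selection for High-Density Surface EMG via Multiclass
    Common Spatial Patterns and Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatial-filter based reduction of high-density surface
    electromyography (HD-sEMG) electrode grids for myoelectric motion
    recognition. Builds multiclass common spatial pattern (CSP) filters by
    joint approximate diagonalization of per-class covariance matrices,
    ranks filter columns by a closed-form Gaussian-mixture mutual
    information between motion class and filtered output, maps the
    top-ranked filters back to physical electrode channels, extracts
    wavelet-packet log-RMS features from the selected channels, and
    evaluates motion classification by stratified cross validation with
    SVM, LDA, KNN and a single-hidden-layer neural network. Includes PCA
    and symmetric FastICA spatial filtering for comparison, a synthetic
    HD-sEMG generator with planted class-dependent spatial activation for
    end-to-end validation, and ggplot2 helpers for electrode-grid
    topography and confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    nnet,
    signal,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
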