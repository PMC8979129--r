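Package: thzQuant
Title: Terahertz Spectral Imaging and GAN-Augmented Deep Classification of
    Pesticide Concentration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometrics pipeline for quantifying analyte
    (carbendazim) concentration classes in a food matrix from terahertz
    time-domain spectroscopy. Simulates paired reference/sample THz
    waveforms with known optical constants, inverts them to refractive
    index and absorption coefficient via the thin-slab transfer-function
    formulas, renders absorption spectra as outer-product images, augments
    scarce classes with a per-class Wasserstein GAN (weight-clipped
    critic), and classifies 13 concentration levels with 18- and 152-layer
    residual networks under a configurable macro-layer freezing protocol.
    Includes SSIM image similarity, analytic FLOP accounting, and
    shallow-learning baselines (SVM with GA/PSO hyperparameter search,
    k-nearest neighbour, naive Bayes, random forest) on identical data
    splits. Networks run on a self-contained CPU engine built on
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    e1071,
    class,
    randomForest
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
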