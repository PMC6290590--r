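Package: wristshapes
Title: Shape and Statistical Feature Derivation from Wrist Accelerometer Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives feature vectors from raw triaxial wrist accelerometer
    recordings for physical-activity assessment. Implements three feature
    families: the seven standard statistical wrist variables computed over
    15-second epochs (mean/SD vector magnitude, arm-angle statistics, and
    FFT-based dominant-frequency and band-power measures); an unsupervised
    bag-of-words representation that learns a codebook of recurring
    acceleration patterns by clustering sliding subsequences and weights
    nearest-atom word counts with augmented tf-idf; and a supervised shape
    feature method that mines recurring motifs per participant and activity
    via a dynamic-time-warping distance score, consolidates them into a
    medoid codebook by hierarchical clustering, and uses mean DTW distances
    to atoms as epoch features. A banded dynamic time warping kernel is
    implemented in C++. Downstream tooling covers sedentary and locomotion
    activity identification with random forests, epoch majority voting,
    label-augmented energy-expenditure (MET) regression, evaluation metrics,
    a seeded synthetic cohort generator for end-to-end testing, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
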