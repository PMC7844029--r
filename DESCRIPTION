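Package: lnspike
Title: Linear-Nonlinear Poisson Encoding Models for Head and Eye
    Self-Motion Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying which behavioral variables a neuron
    encodes from simultaneously recorded behavior and spike trains.
    Implements a cardinal-spline-basis linear-nonlinear (LN) Poisson
    encoding model with penalized maximum-likelihood fitting, 10-fold
    cross-validation and signed-rank forward variable selection;
    derivation of head kinematics (pitch, roll, azimuth, angular
    velocities) from accelerometer and LED tracking data; pupil
    tracking from eye-camera frames; model-derived tuning curves with
    polynomial shape and velocity-subtype classification; population
    statistics (binomial preference tests, entropy, mutual
    information, PCA tuning-space clustering); shuffle-based
    significance controls; and seeded synthetic-data generators for
    open-field and virtual-reality sessions so the whole pipeline can
    be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    graphics,
    utils,
    tools,
    pracma,
    jsonlite,
    png,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
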