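Package: taskobs
Title: Task-Based Image Quality Assessment with Channelized Hotelling
    Observers and Autoencoder-Learned Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for objective, task-based
    assessment of imaging systems via numerical observers.  Provides a
    lumpy stochastic object model imaged through a stylized Gaussian
    point-response parallel-hole-collimator system with Gaussian or mixed
    Poisson/Gaussian noise; image-space Hotelling observers (direct and
    covariance-matrix-decomposition estimates with regularized
    pseudoinverse); reference channel families for the channelized
    Hotelling observer (Laguerre-Gauss, convolutional Laguerre-Gauss,
    partial least squares, nonprewhitening matched filter); tied-weight
    linear autoencoder channel learning with conventional or
    task-informed reconstruction losses; and ROC analysis with empirical
    and binormal-fit AUC, bootstrap uncertainty, and test-statistic SNR.
    Includes config-driven runners for dataset-size sweeps and
    domain-shift/amalgamation generalization studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
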