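Package: plmbci
Title: Piecewise-Linear Feedback-Control Modelling of Closed-Loop BCI Cursor Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, fits, and optimizes closed-loop intracortical
    brain-computer interface (iBCI) cursor control with a piecewise-linear
    feedback-control model (PLM) of the user. The simulated user acts on
    delayed visual feedback through a forward model of the decoder dynamics,
    issues a control vector composed of a distance-weighted push toward the
    target and a speed-weighted damping term, and is corrupted by
    autoregressive Gaussian decoding noise with optional signal-dependent
    variance scaling. The package fits a user-specific model from one block
    of closed-loop data, predicts target-acquisition performance under
    held-out decoder gain/smoothing and task conditions, and uses simulation
    to optimize decoder parameters: gain and smoothing sweeps, dwell-time
    selection for a grid keyboard by achieved bit rate, and nonlinear speed
    transforms (exponent and piecewise-linear). A calibration benchmark
    shows how velocity-Kalman recalibration with intention re-estimation
    drifts away from sweep-optimal gain and smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
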