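Package: africo
Title: Adaptive State-Feedback Echo State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and evaluation of echo state networks (ESNs) with
    adaptive state feedback. Implements the two-stage AFRICO scheme: an
    Extended Kalman Filter jointly estimates the reservoir state together
    with the input and state-feedback weights, and a sparse polynomial
    readout is then constructed by Orthogonal Forward Regression with the
    Error-Reduction-Ratio criterion and validation-based stopping. Includes
    a FORCE (recursive least squares) output-feedback baseline, synthetic
    benchmark generators (random stable linear systems, a linear-nonlinear
    cascade, NARMA10), signal-to-noise-ratio noise injection, normalised
    mean squared error evaluation, frequency-response comparison for linear
    models, and a replicated-experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
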