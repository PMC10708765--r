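Package: facedep
Title: Explainable Depression Detection from Facial-Expression Time Series
Version: 0.1.0
Authors@R:
    person("facedep", "developers", email = "facedep@example.org", role = c("aut", "cre"))
Description: Tools for screening depression from per-frame facial features
    (head pose, eye gaze, and facial action units) extracted by tools in the
    OpenFace family. Provides feature ingestion and selection for the
    49-column OpenFace dialect, severity-to-binary target mapping with label
    smoothing, stratified cohort splitting with duplication balancing, a
    nine-member model zoo crossing early/intermediate/late feature fusion
    with Bi-LSTM, window-block LSTM and transformer backbones (implemented
    with an in-package reverse-mode autodiff and compiled recurrent
    kernels), support-weighted and macro evaluation reports, integrated
    gradients attribution with ranked impact summaries, and a synthetic
    cohort generator with planted, effect-size-controlled depression
    signatures for end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
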