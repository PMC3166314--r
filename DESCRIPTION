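Package: nirsgls
Title: Noise Reduction and Generalized Least Squares Inference for fNIRS
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Denoising and single-subject statistical inference for
    functional near-infrared spectroscopy (fNIRS) hemodynamic time series.
    Implements recursive removal of quasi-periodic systemic artifacts
    (cardiac, respiratory and blood-pressure waves) by time-warped
    signature-template subtraction, targeted motion-artifact correction
    (ripple detection with piecewise-linear segmentation and local cubic
    reconstruction, spike interpolation), and general linear model
    inference under power-law (1/f) serial correlation via feasible
    generalized least squares: high-pass precoloring, spectral whitening
    from a log-log periodogram fit, and their combination. Includes a
    synthetic-data module (phase-randomized colored noise, block designs,
    artifact simulacra) and Monte Carlo calibration experiments verifying
    near-uniform null p-values, plus a simple hierarchical group model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
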