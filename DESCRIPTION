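Package: voltacal
Title: Chemometric Calibration of Overlapping Differential-Pulse Voltammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate calibration pipeline for the simultaneous
    voltammetric quantification of four non-steroidal anti-inflammatory
    drugs (paracetamol, diclofenac, naproxen, aspirin) from strongly
    overlapping differential-pulse voltammograms. Provides a synthetic
    voltammogram generator with concentration-proportional Gaussian
    oxidation peaks and fixed interferents, full-factorial and
    Box-Behnken experimental designs, second-order response-surface
    fitting and multi-response optimization of the pulse-voltammetry
    parameters, Daubechies wavelet compression of the current traces to
    approximation coefficients, partial-least-squares and
    Bayesian-regularized neural-network calibration models, and
    analytical figures of merit (obtained-versus-expected regression,
    recovery yield, limits of detection and quantification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
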