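Package: detrack
Title: Dual-Energy Markerless Tumor Tracking Simulation and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired high/low-kVp projection sequences of a
    moving-tumor thorax phantom with exactly known motion, forms dual-energy
    soft-tissue and bone images by weighted logarithmic subtraction, applies
    four noise-reduction variants (simple smoothing, anticorrelated noise
    reduction, noise clipping, and their composition), tracks the tumor by
    band-pass-filtered normalized cross-correlation template matching,
    estimates ground truth with a constant-acceleration Kalman filter, and
    scores tracking with success-rate, root-mean-square-error and
    missing-frame metrics over a band-pass parameter sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
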