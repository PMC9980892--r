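Package: eegtemplates
Title: Template-Based EEG Source Localization for Functionally Defined
    Visual Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds scalp-topography templates for functionally defined
    cortical regions of interest (ROIs) by averaging per-participant
    forward projections, and estimates each region's contribution to
    group-averaged EEG via Tikhonov-regularized linear regression with
    L-curve and generalized cross-validation selection of the
    regularization weight.  Includes a synthetic multi-participant head
    model population (three-concentric-sphere forward physics), an
    ERP-style simulation battery with controlled signal-to-noise ratio,
    noise structure, montage size and interfering sources, crosstalk
    analysis, ROC-based recovery metrics, and bootstrap group inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
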