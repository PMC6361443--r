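Package: cagepulse
Title: Home-Cage Activity Analysis for Capacitive Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for continuous home-cage activity monitoring of
    group-housed mice with an under-cage board of 12 capacitive electrodes
    sampled at 4 Hz. Converts raw capacitance signals into activation events
    via a thresholded first-order difference, bins them into day/night and
    cage-change-cycle activity series, decomposes activity over four floor
    areas, and quantifies responses to lights-on, lights-off and cage-change
    interventions with a full-width-half-maximum paradigm. Includes a
    stochastic cage simulator (two-state random-walk mice over a capacitive
    electrode grid) with full ground truth, so every stage of the pipeline can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
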