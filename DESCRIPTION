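Package: lmpcalib
Title: Calibration and Evaluation of Pig Carcass Grading Equations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the EU pig-carcass grading-device calibration
    workflow: simulation of carcass populations with realistic hot-weight,
    backfat and loin-depth structure; stratified selection of dissection
    samples over fat and weight groups; partial- and total-dissection lean
    meat percentage computation with scaling-factor bias correction;
    partial least squares fitting of device prediction equations with
    leave-one-out PRESS cross-validation of RMSEP and an authorization
    verdict; and SEUROP classification with population-level comparison of
    prediction equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
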