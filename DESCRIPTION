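Package: amylokin
Title: Autocatalytic Amyloid Aggregation Kinetics and Screening Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of thioflavin-T (ThT) amyloid aggregation
    time courses with the two-parameter autocatalytic
    nucleation-elongation model: closed-form evaluation of the
    fraction-aggregated sigmoid, extraction of nucleation (k_n) and
    elongation (k_e) rate constants by bounded nonlinear least squares,
    and tangent-construction characteristic times (lag, half, end).
    Includes endpoint screening arithmetic for in vitro aggregation
    inhibition, fibril disaggregation, and in cellulo thioflavin-S
    inclusion-body assays, plus a synthetic plate-reader data generator
    emulating triplicate measurements with multiplicative noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
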