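Package: bbdopt
Title: Box-Behnken Response-Surface Modelling and Desirability
    Optimization for Ultrasound-Assisted Pigment Extraction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for three-factor Box-Behnken experimental designs and
    their downstream analysis: factor coding, second-order (quadratic)
    response-surface models fitted by ordinary least squares with ANOVA
    and a centre-point lack-of-fit test, spectrophotometric assay
    conversions (chlorophyll a+b, carotenoid and phycocyanin
    concentrations, pigment yield, ABTS Trolox equivalents, Folin-
    Ciocalteu gallic-acid equivalents), and Derringer-type desirability
    analysis for simultaneous multi-response optimization.  Ships the
    15-run ultrasound-assisted Spirulina platensis extraction study as a
    built-in fixture together with a synthetic-experiment generator with
    known quadratic truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
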