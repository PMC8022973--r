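Package: nemaquant
Title: Quantification Pipelines for Nematode Reporter Assays and Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of three quantification
    procedures for plant-parasitic nematode reporter-gene experiments:
    pixel-threshold scoring of fluorescence micrographs of individual worms
    (crop, invert, brightness/contrast/intensity adjustment, background-variance
    pixel counting), nonlinear least-squares fitting of luminescence decay
    kinetics with half-life comparison between treated and control wells, and
    gonad/body morphometry statistics with exact Mann-Whitney U tests and
    compact letter displays. Ships synthetic-data generators that emulate each
    assay readout (worm images with gut autofluorescence, plate-reader time
    series, per-group morphometry tables) so the whole pipeline is verifiable
    without original micrographs or plate-reader files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
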