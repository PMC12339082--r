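Package: osteoquant
Title: Quantitative Backscattered Electron Imaging of Bone: Mineralization,
    Lacunae and Trabecular Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for backscattered-electron images of
    longitudinal bone sections. Converts 8-bit gray levels to calcium
    weight-percent via a two-point carbon/aluminum standards calibration,
    computes bone mineralization density distributions (BMDD) and their
    scalar descriptors (CaMean, CaPeak, CaWidth, CaLow, CaHigh), segments
    osteocyte lacuna sections with size gating and Crofton perimeters,
    measures trabecular histomorphometry (BV/TV, Tb.Th, Tb.N) in
    primary- and secondary-spongiosa bands below the metaphyseal
    mineralization front, measures growth-plate thickness, and runs
    normality-gated two-group and two-way factorial cohort statistics.
    Includes a synthetic qBEI image and cohort generator with planted,
    recorded ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    tiff,
    png,
    yaml,
    jsonlite,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
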