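Package: bifocal
Title: Bifocal Convolutional Detection and Bimodal Heatmap Fusion for
    Whole-Slide Immunohistochemistry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell analysis of immunohistochemically stained
    whole-slide image tiles. Detects immunoreactive cells with a
    two-branch ("bifocal") convolutional neural network fed co-centred
    32x32 and 64x64 patch pairs, converts sliding-window predictions to
    pseudo-colour heatmaps, filters detections by an Otsu-statistic
    discriminability threshold, segments and measures discriminable
    cells (area, perimeter, compactness, minimum pixel intensity), fuses
    cell heatmaps with companion H&E morphological-feature heatmaps via
    single-level discrete wavelet transform coefficient averaging, and
    reports per-feature cell densities. Includes a seeded synthetic
    stained-tissue generator so the full workflow is testable without
    external slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
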