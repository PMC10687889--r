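Package: fastcar
Title: Ambient RNA Correction for Droplet Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Profiles ambient RNA from low-UMI ("empty droplet") libraries in
    droplet-based single-cell RNA-seq data and removes it from cell libraries
    by clamped subtraction of each contaminated gene's maximal ambient count.
    Includes 10x Genomics MatrixMarket input/output, threshold-selection
    diagnostics (removal profiles across a grid of empty-library thresholds,
    per-gene expressing versus non-expressing summaries, pseudo-bulk
    aggregation), a droplet-data simulator with per-count native/ambient
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
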