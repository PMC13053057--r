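Package: tocstamp
Title: Tumor-on-Chip Live-Imaging Analysis of CAF-Mediated Chemoprotection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cancer-cell death and tumor-fibroblast proximity in
    tumor-on-chip time-lapse videos. Implements a static-cell variant of the
    STAMP video-analysis method (adaptive Bradley thresholding of the red
    channel, a temporal-persistence tumor mask, dilation-based
    foreground/background rings), caspase-reporter apoptosis event calling
    with windowed survival and apoptosis-rate statistics, transmission-channel
    CAF segmentation with a pluggable backend, and per-cell tumor-CAF
    proximity metrics (contact counts below 18 um, minimum boundary distance,
    intersection-over-union inside an 82 um disc) stratified by late cell
    fate. A seeded synthetic time-lapse generator with full ground truth makes
    every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    tiff,
    withr,
    EBImage,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
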