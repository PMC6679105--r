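Package: semseason
Title: Seasonal Dynamics of DNA Methylation from Multi-Timepoint Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of seasonally methylated cytosines
    (SeMCs) from per-cytosine bisulfite sequencing counts sampled repeatedly
    across a year. Implements per-site minimum pairwise Fisher exact testing
    across time points with Storey q-value false discovery control, bulk and
    windowed methylation profiles against repeat density, per-repeat seasonal
    methylation series, bisulfite conversion-rate estimation from an
    unmethylated spike-in, and the association between gene-body CG
    methylation and the seasonal average and range of RNA expression. Includes
    a fully seeded synthetic methylome generator with planted ground truth for
    calibration and power studies, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
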