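Package: loopeval
Title: Evaluation Metrics and Simulators for ChIA-PET and HiChIP Loop Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Benchmarking toolkit for chromatin loops called from targeted
    chromatin conformation capture experiments (ChIA-PET and HiChIP).
    Implements quality and reliability metrics for loop sets -- uniquely
    mapped valid PET rate, peak co-occupancy of loop anchors, local and
    global enrichment scores, accuracy against gold-standard contact sets,
    activation rate of enhancer/promoter loops, and resolution-level
    profiles -- together with the construction of gold-standard and matched
    false loop sets, distance-decay Poisson simulation of ChIA-PET contacts,
    coverage-filtered HiChIP simulation, and a self-contained synthetic
    fixture generator. All functions take plain data frames of genomic
    intervals and return tibbles, so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
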