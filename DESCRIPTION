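Package: ebscreen
Title: Clonal Deconvolution and Perturbation Statistics for CRISPR Screens
    in Embryoid Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR transcription-factor screens read out by
    single-cell RNA-seq in embryoid bodies (EBs). Implements guide RNA
    assignment from UMI and read counts, organoid-barcode clonotype
    deconvolution for monoclonal EBs, cell-type-composition perturbation tests
    with a non-targeting-control (NTC) empirical null, k-nearest-neighbour
    perturbation enrichment, clonal-bottleneck diagnostics, reciprocal
    non-negative least squares cell-type correspondence across datasets, and a
    synthetic EB screen simulator that reproduces stochastic clonal
    jackpotting in mosaic EBs and its monoclonal rescue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
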