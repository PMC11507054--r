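Package: slcontinuum
Title: Malignant-Continuum Analysis of Serrated-Lesion Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the stepwise malignant transformation of
    serrated colorectal lesions from multi-sample single-cell RNA-seq.
    Provides per-sample two-part (hurdle) differential expression of a
    malignant epithelial subtype against a pooled normal reference,
    ordering of samples along a malignant continuum by fitting a principal
    curve to the principal components of the per-sample log2 fold-change
    profiles, Spearman gene-trend discovery along the continuum,
    reference-anchored copy-number inference from smoothed expression with
    chromosome-arm gain/loss percentages, control-matched gene-program
    (module) scoring with cell-cycle phase assignment, stage-wise cell-type
    composition testing, and a negative-binomial simulator that plants a
    known continuum, copy-number segments and gene programs for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
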