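Package: atacmix
Title: Cell-Type Deconvolution and Sensitivity Analysis for ATAC-seq Cell Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions in heterogeneous samples from
    chromatin-accessibility (ATAC-seq) peak count matrices. Pure-population
    replicate profiles are TMM-normalized, cell-type signature peaks are
    selected by unequal-variance t-tests with condition-number-guided
    signature sizing, and mixture samples are deconvolved with a
    non-negative least-squares linear mixing model. Includes a negative
    binomial simulator of titrated cell mixtures, a Poisson-background peak
    detection rule for sensitivity analysis across cell proportions and
    sequencing depths, and BED/TSV interval and count-matrix IO with
    TSS-distance annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    edgeR,
    pracma,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
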