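Package: phenogeno
Title: Statistics for Testing Whether a Cell Phenotype Is Genomically Encoded
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a cell phenotype (such as the breast
    cancer stem cell state) is written in the genome. Implements selection of
    variant sites whose allele frequency rises between a parental population
    and a phenotype-enriched derivative (Fisher's exact test with a direction
    rule), mutation-hotspot calling from inter-SNV distances under an
    exponential null with run-length-encoding segmentation and hypergeometric
    significance, and a single-cell genomic-concordance framework built on
    per-position base weights, genetic distances, position-specific
    sequencing-error rates, binomial background tests, permutation of group
    labels, and the case-permutation ratio. A synthetic-data generator
    reproduces the statistical structure every stage assumes, so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Config/testthat/edition: 3
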