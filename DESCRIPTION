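Package: traitprop
Title: Trait Relevance Scoring for Single-Cell Chromatin Accessibility via Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps fine-mapped GWAS variants to their relevant cellular context
    at single-cell resolution from scATAC-seq peak-by-cell count matrices.
    Computes per-cell bias-corrected trait-enrichment Z-scores by weighted
    chromatin-accessibility deviations, selects seed cells, builds a mutual
    k-nearest-neighbor cell graph on a TF-IDF/LSI embedding, propagates seed
    probability mass by random walk with restart, and rescales the stationary
    distribution into a per-cell trait relevance score (TRS). A degree-matched
    permutation test classifies cells as trait-enriched or depleted, and a
    binomial read-sampling simulator generates ground-truth synthetic
    single-cell datasets for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
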