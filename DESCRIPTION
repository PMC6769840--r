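Package: shallowcnv
Title: Maternal Copy Number Variant Discovery from Shallow Whole-Genome
    Sequencing of Plasma DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A bin-based copy number variant (CNV) discovery pipeline for
    low-coverage (~0.3x) whole-genome sequencing of cell-free plasma DNA,
    as produced by non-invasive prenatal testing. Unique read starts are
    counted in fixed 20 kbp bins, corrected for GC bias by LOESS
    detrending, denoised by principal-component projection against a
    euploid control cohort, masked for low-complexity regions, and
    segmented by circular binary segmentation with a permutation test.
    Segments at least 600 kbp long whose mean diploid ratio deviates by at
    least 60% of a single-copy shift are reported as maternal CNV calls,
    annotated against known-variant interval databases, attributed to
    coding versus non-coding sequence, and aggregated into
    population-level summaries with per-variant carrier frequencies via
    reciprocal-overlap clustering. A synthetic-cohort generator with
    machine-readable truth sets supports end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
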