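Package: exocnv
Title: Copy-Number Variant Calling from Exome Read Depth with
    Mappability Filtering and Resampling-Based Reproducibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects copy-number variants (CNVs) from exome-sequencing
    read depth. Targets with low 35-mer mappability are excluded before
    counting, a reference panel of the most correlated control samples is
    aggregated per test sample, and a three-state hidden Markov model with
    beta-binomial emissions segments each chromosome into deletion, normal
    and duplication states with log10 Bayes factors. An iterative
    recalling framework against random control subsets scores the
    reproducibility of every call, and a benchmarking module builds
    SNP-array-derived truth sets through a staged filtering cascade and
    computes stratified sensitivity and false-discovery-rate summaries.
    A synthetic-cohort simulator makes the full workflow runnable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
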