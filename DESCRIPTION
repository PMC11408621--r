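Package: loopqtl
Title: Mapping Interaction QTLs from Donor-Resolved HiChIP Chromatin Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies interaction QTLs (iQTLs): genetic variants whose
    genotype and allelic state are associated with the strength of HiChIP
    chromatin loops across a donor cohort. Implements candidate SNP-loop
    pairing over anchor windows, allele-specific read counting from
    paired-end contacts, genotype-trend and allele-paired testing with
    Benjamini-Hochberg control, a four-condition filtering cascade,
    multi-loop and connectivity-QTL detection via connected-component
    aggregation of loops with genotype-stratified contact maps, and a
    loop-matched resampling null for overlap enrichment. Ships a seeded
    synthetic-cohort generator with planted effects so the whole pipeline
    is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
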