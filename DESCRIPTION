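Package: chromstrat
Title: Stratifying Chromatin Remodellers by Integrative Epigenomic Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative epigenomic analysis toolkit that stratifies
    ATP-dependent chromatin remodellers into functional groups from their
    ChIP-seq binding profiles. Provides readers for the common interval and
    per-position formats (BED, BEDPE, bedGraph, FASTA, methylation count
    tables), exact interval algebra, a Monte-Carlo randomization test for
    segment-annotation overlap enrichment with an analytic oracle, rule-based
    classifiers for promoters, enhancers, chromatin states, CpG islands and
    chromatin-loop anchors, signal score matrices, methylation and
    accessibility summaries, expression linkage via TPM and rank-sum testing,
    genome-architecture partitioning, and a seeded synthetic-epigenome
    generator with a ground-truth manifest so the entire analysis can be run
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
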