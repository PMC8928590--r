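Package: spermcnv
Title: Copy-Number Variant Interval Statistics for Single-Sperm Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream interval statistics for structural-variant calls from
    single-sperm (and companion trio) short-read sequencing: length and
    support-read filtering of LUMPY-style SV VCFs, segmental-duplication
    fragment merging and summarisation, repeat-content profiling with a
    random-region permutation enrichment test, chromosome-arm positional
    enrichment testing, multi-group CNV sharing (Venn) analysis, and
    Fisher/Benjamini-Hochberg annotation enrichment. Ships a synthetic-data
    generator that emulates multi-sample haploid sperm call sets with planted
    positional and repeat co-location structure, so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    vcfR,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
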