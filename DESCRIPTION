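Package: meripkit
Title: MeRIP-Seq m6A Peak Calling, Differential Methylation and
    Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for N6-methyladenosine (m6A) epitranscriptomics
    from MeRIP-seq experiments. Implements UMI-based consensus
    deduplication of PCR duplicate families, fixed-window Fisher exact
    peak calling of IP versus Input libraries with adjacent-window
    merging, two-condition differential and condition-specific peak
    detection, peak annotation against gene functional regions (5'UTR,
    CDS, 3'UTR, non-protein exon) with metagene profiles, k-mer motif
    enrichment with RRACH verification, RPKM expression quantification
    and fold-change classification with methylation-expression overlap
    analysis, alignment summaries, hypergeometric gene-set
    over-representation, and qPCR relative quantification by the
    2^-ddCt method. Includes a seeded synthetic-data generator that
    emulates stranded IP/Input libraries with known ground truth so
    every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
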