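Package: uaRNAdiff
Title: Differential Analysis of Upstream Antisense RNAs from 3'-End
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies upstream antisense RNAs (uaRNAs, also called
    PROMPTs) from strand-specific 3'-end sequencing data such as 3'READS.
    Calls poly(A)-site-supporting (PASS) reads by their non-templated
    poly(A) tails, assigns read 3' ends to protein-coding genes as sense
    or upstream-antisense using strand-aware windows, tests per-gene
    changes in the uaRNA:sense read balance between two conditions with a
    two-sided Fisher exact test, summarises global UP/DN enrichment with
    a one-degree-of-freedom chi-squared test, and produces poly(A)-site
    and TSS-anchored descriptive profiles. A seeded simulator of toy
    genomes, annotations and 3'-end reads with truth labels supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
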