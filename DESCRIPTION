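Package: crisprtrie
Title: CRISPR Guide RNA Design via FM-Index Off-Target Enumeration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A guide RNA (gRNA) design engine for CRISPR-Cas systems built on
    a Burrows-Wheeler-transform full-text index. Exhaustively enumerates gRNA
    off-target sites in arbitrary genomes within mismatch and bulge budgets by
    a pruned depth-first traversal of the implicit reverse-prefix trie of
    backward-search states, with wildcard semantics for protospacer-adjacent
    motifs (PAMs). Aggregates cutting-frequency-determination (CFD) penalties
    into a specificity score, constructs genome-wide gRNA databases with
    SAM-format output and hex-encoded off-target summaries, designs
    high-specificity gene-targeting libraries through a filter cascade with
    safe-targeting and non-targeting controls, and designs allele-specific
    gRNAs for hybrid diploid genomes from variant calls. Includes a synthetic
    fixture generator (genomes, annotations, variants, planted off-target
    sites) and a brute-force scanner used as an independent verification
    oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
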