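Package: saltmir
Title: Small RNA-Seq Analysis of Salt-Stress miRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for two-condition small RNA sequencing
    studies of the kind used to profile salt-stress-responsive microRNAs
    in crops such as faba bean (Vicia faba). Covers read cleaning and
    collapsing to unique tags, length-distribution summaries, annotation
    of tags to small-RNA categories under a single-assignment priority
    rule, novel miRNA candidate detection by precursor excision and
    weighted base-pair-maximization folding, TPM quantification with a
    zero-count floor, the exact two-library Poisson (Audic-Claverie)
    digital-expression test with Bonferroni and false-discovery-rate
    control, and hypergeometric GO/KEGG term enrichment. A synthetic-data
    generator with known per-locus fold changes makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
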