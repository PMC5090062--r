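Package: miRheat
Title: miRNA Expression Dynamics During the Heat-Shock Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing small-RNA-seq miRNA
    expression dynamics across inbred strains subjected to heat shock.
    Implements read counting over a miRBase-dialect annotation, consensus
    negative-binomial differential expression with classification of
    miRNAs whose interstrain differences are levelled by heat shock,
    polynomial time-course profile selection with backward stepwise
    regression and YS1-distance hierarchical clustering, arm-switching and
    A-to-G / T-to-C editing detection, consensus target voting, GO
    enrichment with the elim decorrelation algorithm, and permutation-based
    GO semantic-similarity testing. A synthetic-data module generates every
    input with ground-truth labels so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
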