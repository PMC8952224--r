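Package: ceRNAswitch
Title: Competing-Endogenous-RNA Network Discovery for Transcriptomic
    Phenotype-Switch Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end downstream analysis of a two-condition bulk RNA-seq
    study of vascular smooth-muscle phenotypic switching: negative-binomial
    differential expression with tiered significance thresholds, five-step
    long non-coding RNA (lncRNA) candidate filtering with coding-potential
    scoring (open reading frame length and Fickett TESTCODE statistic),
    cis (100 kb genomic window) and trans (RNA-RNA hybridization free
    energy) lncRNA target prediction, lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) network construction under the
    direction-opposition rule, maximal clique centrality (MCC) hub scoring
    of a protein-protein interaction network, key ceRNA axis ranking by
    expression correlation, and over-representation enrichment analysis.
    Includes a seeded synthetic-study generator with planted ground truth
    for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    igraph,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
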