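Package: peachscan
Title: Desk-Scale Population Genomics for Wild Peach: BSA Mapping, Sweep
    Scans, Gene Origin and Divergence Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A compact toolkit for the bespoke computations used in
    comparative and population genomics of peach and its wild relatives:
    k-mer histogram genome-size estimation, delta-SNP-index bulked
    segregant analysis (QTL-seq style) of a backcross population, a
    windowed two-group selective-sweep scan (nucleotide diversity ratio,
    Tajima's D, Hudson's Fst), best-alignment-score assignment of gene
    origin for hybridization analysis, pan-genome gene-family
    presence/absence classification, and the fourfold-degenerate
    transversion (4DTv) divergence statistic.  A synthetic-data module
    generates backcross pools, two-group genotype matrices with planted
    sweeps, k-mer histograms, codon-aligned gene pairs and donor/recipient
    gene sets so that every stage is testable without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
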