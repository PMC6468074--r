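Package: gcapr
Title: Gene Capture Marker Refinement for Exon-Based Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates single-copy exon markers from target-enrichment (gene
    capture) experiments and refines hybridization bait design a posteriori.
    Identifies target exons in assembled contigs by translated Smith-Waterman
    alignment, screens putative paralogs by best-hit genomic location, selects
    phylogenetically decisive loci across required clade groups, soft-masks
    read-depth anomalies before re-tiling 120-nt baits at 2x coverage, and
    summarises marker quality (length, GC content, pairwise p-distance,
    parsimony consistency and retention indices, RC50 coverage evenness) and
    flanking-region variability.  Includes seeded synthetic-data generators
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    seqinr,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
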