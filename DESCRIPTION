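Package: mirseedclust
Title: SNPs in miRNA Seed Regions: Mapping, Allele-Dependent Target
    Overlap, and Cluster Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates single-nucleotide polymorphisms (SNPs) falling in
    the seed regions (mature positions 2-8) of human microRNAs with
    strand-aware coordinate arithmetic, predicts allele-dependent target
    gene sets by canonical seed matching (8mer, 7mer-m8, 7mer-A1, 6mer
    site types) against 3'UTR collections, quantifies the functional
    effect of a seed SNP as the cosine-similarity percent overlap between
    reference- and derived-allele target sets, groups miRNA precursors
    into genomic clusters by the 10 kb same-strand rule, and tests
    whether seed-SNP-carrying miRNAs are enriched in clusters (Pearson
    chi-square) and whether clustered seed SNPs have milder target-set
    rewiring (two-sample t-test), with a generic hypergeometric
    over-representation test for miRNA annotation sets. Includes a
    deterministic synthetic-data generator (GFF3/FASTA/VCF/GMT) with
    planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stringi,
    vcfR,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
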