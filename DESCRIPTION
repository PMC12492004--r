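Package: karyotypeR
Title: Synteny Blocks, Chromosomal Rearrangement Indices, and K2P
    Distances for Comparative Karyotype Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds oriented collinear synteny blocks from one-to-one
    ortholog anchors between two genomes, classifies blocks into
    rearrangement calls (collinear, inversion, inter-chromosomal
    translocation/insertion), detects macro-fragment inversions, computes
    breakpoint-based rearrangement indices (C_i, S_i, R_i) that rank genome
    shuffling between species, and extracts genes inside rearranged blocks
    for downstream enrichment. Also provides Kimura 2-parameter distances
    with pairwise deletion for marker-gene species delimitation, and a
    seeded karyotype-evolution simulator (inversions, translocations,
    fusions, fissions) with ground-truth operation logs for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
biocViews: ComparativeGenomics, Genetics, Phylogenetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
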