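Package: intronfam
Title: Family Classification and Gain-Loss History of Plant Mitochondrial
    Group II Introns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for categorizing streptophyte (land plant and charophyte
    algae) mitochondrial group II introns into families of related
    paralogues. Implements sensitive seed-and-extend nucleotide similarity
    search with Karlin-Altschul significance statistics, the
    most-distant-ortholog (MDO) clustering criterion that groups insertion
    sites into paralogue families, detection of degenerate "fossil" intron
    copies in intergenic spacers, annotation and similarity clustering of
    intron-borne maturase open reading frames, structural screens for the
    catalytic domain V hairpin and splice-boundary motifs, and weighted
    Sankoff gain-loss parsimony of intron presence/absence over alternative
    land-plant phylogenies. A fully seeded simulator of intron
    retrotransposition, loss, fossilization and maturase decay provides
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
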