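Package: hoxfocus
Title: Phylogenetic Focusing and Hox Protein Annotation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for targeted gene-family phylogenomics
    built around the phylogenetic focusing strategy: per-species protein
    harvest by local alignment search, redundancy reduction, per-species
    gene trees rooted on an outgroup clade, focal-subclade extraction,
    pooled filtering with profile hidden Markov models, and clade-based
    family assignment of unknown sequences.  Companion modules annotate
    Hox protein functional regions (homeodomain, hexapeptide, linker and
    auxiliary motifs), map Hox gene clusters on genomic scaffolds with
    near-identical overlap merging, and simulate proteomes and clustered
    loci with truth tables so that every pipeline stage is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
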