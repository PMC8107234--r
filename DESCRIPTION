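Package: panclade
Title: Genomic Species Delineation, Pangenome Structure, and Gene
    Gain/Loss Histories for Bacterial Clades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genus-scale comparative genomics of bacterial
    genome collections. Computes pairwise average nucleotide identity
    (fragment-based), tetranucleotide usage z-score correlations and
    reciprocal-best-hit average amino-acid identity, and delineates
    genomic species as connected components of the triple-condition
    graph (ANI > 95%, TETRA > 0.99, AAI > 95%), with gray-zone
    reporting and 16S rRNA based naming. Builds orthogroup
    presence/absence matrices by greedy protein clustering, partitions
    them into core/soft-core/shell/cloud categories, estimates
    pangenome openness from power-law fits to rarefaction curves,
    reconstructs a distance-based core-genome species tree, and infers
    per-branch gene gain and loss events by Wagner parsimony. Includes
    a synthetic clade simulator (species tree, gene content evolving by
    gain and loss, Jukes-Cantor sequence evolution, 16S-like marker)
    with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    phytools,
    igraph,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
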