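Package: riboclock
Title: Structural Phylogenomics Chronologies of RNA Substructures and Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs relative evolutionary timelines of RNA secondary-structure
    elements and protein domain superfamilies from structural census data. Decomposes
    aligned RNA secondary structures into stem, hairpin, bulge and unpaired segments,
    codes segment lengths as ordered multistate phylogenetic characters, infers rooted
    trees of substructures by ordered-state (Wagner) maximum parsimony with TBR branch
    swapping and hypothetical-ancestor (Lundberg) rooting, and converts tree depth into
    a node-distance age statistic (nd) on a 0-1 scale. The same machinery gap-codes
    proteome-by-superfamily abundance censuses into 21-state characters to date protein
    domains (nd_P), assembles event timelines (intersubunit bridges, tRNA and r-protein
    contacts), fits the rRNA/protein coevolution regression, and screens ribozyme
    substructures against ancestral rRNA helices with a structure-only local forest
    alignment judged by a dinucleotide-shuffle Z-score null. Includes seeded synthetic
    generators for accretion-style structure alignments and abundance censuses with
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
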