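Package: gophylo
Title: Maximum-Likelihood Phylogenies and Ancestral Genomes from Gene-Order Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs phylogenies and ancestral genomes from signed
    gene-order data (multichromosomal signed permutations in the GRAPPA/MGR
    text format). Genomes are encoded as binary presence/absence vectors over
    gene adjacencies, telomeres and gene families; an asymmetric two-state
    substitution model whose loss/gain rate ratio follows from a uniform
    double-cut-and-join (DCJ) argument drives maximum-likelihood tree search
    (neighbor joining start, nearest-neighbor-interchange hill climbing) with
    optional bootstrap support. Ancestral gene orders are recovered by
    marginal posterior reconstruction of character states followed by
    adjacency assembly through a Travelling Salesperson reduction solved
    exactly (Held-Karp) or heuristically (nearest neighbor plus 2-opt). A
    genome-rearrangement simulator (DCJ, deletion, insertion, duplication)
    generates ground-truthed datasets for validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
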