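Package: plastcmp
Title: Comparative Plastome Structure and Phylogenetic Signal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid genomes:
    quadripartite (LSC/IRb/SSC/IRa) region inference and junction
    expansion/contraction profiling, gene- and intron-loss detection against a
    reference plastid inventory, sliding-window nucleotide diversity with
    highly-polymorphic-region calling, simple indel coding of intron alignments
    with polarity and family-specificity tallies, plastid tRNA cloverleaf
    decomposition and structural typing, and Fitch parsimony mapping of binary
    characters onto a supplied phylogeny. Includes a deterministic synthetic-data
    generator that plants junction geometries, losses, indel events, diversity
    hotspots and tRNA anomalies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
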