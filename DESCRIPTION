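Package: ighdarch
Title: Architecture, Repeat Expansion and Fusion-Origin Analysis of
    Immunoglobulin Heavy-Chain D-Gene Clusters
Version: 0.1.0
Authors@R:
    person("IGHD", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of duplicated immunoglobulin
    heavy-chain diversity (DH) gene clusters: recombination signal sequence
    (RSS) detection with the heptamer/12-bp-spacer/nonamer model, RSS-guided
    DH gene calling and cluster segmentation, native affine-gap global,
    local and semiglobal pairwise alignment with a single percent-identity
    definition, paralog mapping with deletion, transposition and
    missing-family detection, short tandem repeat decomposition and
    cross-paralog copy-number comparison, donor-pair scoring for DH-DH
    fusion origins of ultralong DH genes, and a seeded simulator of
    duplicated-cluster evolution (duplication, point mutation, segmental
    deletion with gene fusion, transposition, repeat expansion) that emits
    FASTA, BED and a replayable machine-readable truth log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
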