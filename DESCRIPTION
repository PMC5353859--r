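Package: secrepath
Title: Secretory-Pathway Network Reconstruction and Omics Overlay
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data model, validation and I/O for a curated reconstruction of the
    mammalian protein secretory pathway (components, subsystems, functional
    groups, protein complexes and their interactions), homology-based transfer
    of the catalogue to a second species from alignment hit tables, count-matrix
    normalisation (CPM/TMM) and expression filtering, Spearman-distance
    average-linkage clustering with multiscale-bootstrap approximately-unbiased
    cluster support, summed-Spearman regulator screening, gene-phenotype
    correlation with an adaptive two-standard-deviation threshold, and network
    overlay of differential expression with complex-level Fisher enrichment.
    Includes synthetic-data generators emulating the statistical structure of
    the supported inputs and a command-line pipeline driver with Cytoscape
    compatible (SIF/GraphML) network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
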