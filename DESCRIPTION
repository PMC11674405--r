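Package: graphspace
Title: Multidimensional Graph Spaces for Connectome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Embeds network nodes as points in a Euclidean space whose axes
    are normalized nodal graph invariants (degree, betweenness, closeness,
    eigenvector, clustering, participation, within-module degree z-score,
    PageRank, average shortest path, subgraph centrality). Provides readers
    and builders for binary and weighted structural and functional
    connectome models (consensus masking, density-matched thresholding),
    internodal and intersubject Euclidean distance analyses at region and
    global scale, degree- and strength-preserving rewiring null models with
    empirical significance (FDR binarization and z screening), Spearman
    correlation atlases of invariants at whole-network and subnetwork scope,
    PCA and Laplacian-eigenmap latent projections, subject-level hold-out
    classification of node superclasses across feature subsets and
    dimensionalities, and a synthetic block-model generator that emulates
    the study conditions so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    e1071,
    pROC,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
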