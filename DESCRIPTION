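Package: clustkit
Title: Multi-Algorithm Clustering for Biological Networks and Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A unified toolkit for clustering weighted biological networks
    and gene-by-array attribute matrices.  Provides seven network-clustering
    algorithms (Markov clustering, affinity propagation, MCODE complex
    detection, Girvan-Newman community detection, connected components,
    transitivity clustering / weighted cluster editing, and spectral
    clustering of similarity networks), attribute clustering (hierarchical
    with Cluster 3.0 semantics, k-means, k-medoid) with silhouette-based
    selection of the number of clusters, edge-weight conversion and
    histogram-based cutoff heuristics, expression-matrix normalization,
    cluster-network and ensemble co-clustering (fuzzy) network construction,
    Java TreeView compatible CDT/GTR/ATR export, and seeded synthetic-data
    generators for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
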