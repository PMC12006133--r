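Package: wgchna
Title: Weighted Gene Co-Expression Hypernetwork Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Construction and analysis of weighted gene co-expression
    hypernetworks. Genes are modelled as nodes and samples as hyperedges of a
    weighted hypergraph; hyperedge weights aggregate pairwise gene correlation
    (or mutual information) within each sample. The hypergraph Laplacian yields
    a gene-gene topological overlap matrix from which co-expression modules are
    detected by average-linkage hierarchical clustering with a dynamic branch
    cut, eigengene-based module merging and membership refinement. Includes
    soft-threshold selection by scale-free fit of the hyperdegree distribution,
    module-trait correlation, hub-gene detection by module membership, export
    of module gene sets, internal (silhouette, Calinski-Harabasz,
    Davies-Bouldin) and external (adjusted Rand, adjusted mutual information)
    clustering metrics, and a seeded planted-module factor-model simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
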