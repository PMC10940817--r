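Package: girnet
Title: Gene Importance Ranking from Per-Cell Weighted Gene Correlation
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Transforms a single-cell gene expression matrix into a
    same-shaped gene importance matrix. For every cell a gene correlation
    network is inferred from a statistical-independence index computed on
    fixed-width expression neighborhoods, edges are weighted by gene
    expression, and genes are scored by the fixed point of a weighted
    PageRank random walk. Downstream tools cover embedding and clustering
    with adjusted-Rand-index benchmarking, Wilcoxon rank-sum marker
    ranking, detection of network-specific ('dark') genes, marker
    subnetwork extraction, and a synthetic-data generator with planted
    gene-dependence modules, dropout, and matched-mean network-only
    contrasts between cell types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    igraph,
    Rtsne,
    uwot,
    cluster,
    kernlab,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
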