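# girnet

Gene importance ranking from per-cell weighted gene correlation networks.

## What it does, and for whom

Single-cell RNA-seq analyses usually start from the gene expression matrix
(GEM), but per-gene readouts are noisy and dropout-ridden, and they ignore
the co-expression context genes act in. girnet is for analysts who want to
ask heterogeneity questions — which cell types are present, which genes
define them — at the *network* level instead. For every cell it:

1. infers a gene correlation network by testing, for each gene pair, whether
   the cells expressing both genes near the focal cell's levels overlap more
   than independence predicts:

   ρ<sub>ij</sub> = n<sub>ij</sub>/n<sub>C</sub> −
   (n<sub>i</sub>/n<sub>C</sub>)(n<sub>j</sub>/n<sub>C</sub>),

   with fixed expression windows of 0.1·n<sub>C</sub> cells, standardised by
   the random-subset-overlap null and tested one-sided at α = 0.01;
2. weights edges by expression, W<sub>ij</sub> = E<sub>i</sub> / Σ<sub>m∈L(j)</sub> E<sub>m</sub>
   — the probability that a random walker at gene j steps to neighbour i;
3. scores every gene with the fixed point of the damped walk
   PR<sub>i</sub> = (1−d) + d·Σ<sub>j∈L(i)</sub> PR<sub>j</sub>·W<sub>ij</sub>, d = 0.85.

The per-cell scores assemble into a gene importance matrix (GIM) with
exactly the shape and identifiers of the input GEM, so embeddings,
clustering, Adjusted-Rand-Index benchmarking, and Wilcoxon marker ranking
run on it unchanged. On top of that the package finds **dark genes** —
genes that are cluster-specific by network importance but not by
expression — and extracts aggregated marker subnetworks per cluster. A
degree-matrix (NDM) baseline and a synthetic-data generator with planted,
jointly bursting gene modules complete the test bench.

## Worked example

Three cell types whose planted gene modules differ **only in wiring** —
every gene has the same marginal expression distribution in every type:

```r
library(girnet)

sim <- make_fixture("network_only", seed = 0)
gem <- preprocess(sim$gem)        # filter, log-transform, HVG selection
gem
#> ExpressionMatrix: 60 genes x 490 cells [stage: hvg]

gim <- build_gim(gem)             # per-cell networks -> weighted PageRank
gim
#> ImportanceMatrix: 60 genes x 490 cells [damping: 0.85]

truth <- sim$truth$labels[match(gem$cell_ids, sim$gem$cell_ids)]
adjusted_rand_index(cluster_cells(gim, "kmeans", k = 3, seed = 0), truth)
#> 0.188
adjusted_rand_index(cluster_cells(gem, "kmeans", k = 3, seed = 0), truth)
#> 0.012
```

Expression-based k-means is blind to the types (ARI ≈ 0.01, chance level)
while the same clustering on importance recovers substantial structure
(ARI ≈ 0.19): the walk converts wiring differences into per-gene scores.
The planted hubs surface as dark genes:

```r
head(find_dark_genes(gim, gem, truth), 4)
#>   gene_id cluster spec_gim spec_gem
#> 1    g001   type1     2.27    1.036
#> 2    g004   type1     1.94    1.034
#> 3    g008   type1     1.61    0.985
#> 4    g002   type1     1.56    0.983
```

`g001` is the planted hub of type 1's module: its importance is 2.3-fold
specific to type 1 (floor-corrected in/out ratio) while its expression
ratio is 1.04 — indistinguishable across types, exactly what a dark gene
is. A command-line front end (`inst/cli/girnet.R`) exposes the same
pipeline as `simulate`, `preprocess`, `gim`, `ndm`, `cluster`, `markers`
and `darkgenes` subcommands.

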