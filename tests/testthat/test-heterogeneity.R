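test_that("adjusted Rand index handles the canonical cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "b", "a", "b"), c("x", "y", "x", "y")), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  # crossed labelling: every within-pair of one partition is split by the other
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               ari_paircount(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI is symmetric, label-name invariant, and matches references", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    got <- adjusted_rand_index(a, b)
    expect_equal(got, adjusted_rand_index(b, a))
    relab <- c("z", "q", "m")[a]
    expect_equal(adjusted_rand_index(relab, b), got)
    expect_equal(got, ari_paircount(a, b))
  }
  # independent package cross-check
  set.seed(42)
  a <- sample(1:4, 40, replace = TRUE); b <- sample(1:4, 40, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
})

test_that("clustering separates well-separated planted types", {
  sim <- simulate_gem(n_cells = 90, n_genes = 20, n_types = 3,
                      modules_per_type = 1, module_size = 4,
                      dependence_strength = 0, mean_shift = 3,
                      dropout_rate = 0, seed = 43)
  gem <- log_transform(sim$gem)
  lab <- cluster_cells(gem, "kmeans", k = 3, seed = 0)
  expect_gte(adjusted_rand_index(lab, sim$truth$labels), 0.95)
  lab_h <- cluster_cells(gem, "hierarchical", k = 3)
  expect_gte(adjusted_rand_index(lab_h, sim$truth$labels), 0.95)
})

test_that("duplicated cells co-cluster and k = n gives singletons", {
  set.seed(44)
  v <- matrix(stats::rlnorm(60), 6, 10)
  m <- expression_matrix(cbind(v, v), sprintf("g%d", 1:6),
                         sprintf("c%d", 1:20))
  for (method in c("kmeans", "hierarchical", "kmedoids")) {
    lab <- cluster_cells(m, method, k = 4, seed = 1)
    expect_identical(lab[1:10], lab[11:20])
  }
  distinct <- expression_matrix(v, sprintf("g%d", 1:6), sprintf("c%d", 1:10))
  lab <- cluster_cells(distinct, "kmeans", k = 10, seed = 1)
  expect_length(unique(lab), 10)
  expect_error(cluster_cells(distinct, "kmeans", k = 1), "k must be")
})

test_that("embeddings are seeded, 2-D, and respect rank structure", {
  set.seed(45)
  v <- outer(stats::runif(8), stats::runif(30))   # rank-1 matrix
  m <- expression_matrix(v, sprintf("g%d", 1:8), sprintf("c%d", 1:30))
  pc <- embed(m, "pca")
  expect_identical(dim(pc), c(30L, 2L))
  expect_lt(stats::var(pc[, 2]), 1e-20)
  ts1 <- embed(m, "tsne", seed = 7)
  ts2 <- embed(m, "tsne", seed = 7)
  expect_identical(ts1, ts2)
  um1 <- embed(m, "umap", seed = 7)
  expect_identical(dim(um1), c(30L, 2L))
  # pca separates two strongly shifted groups
  v2 <- v; v2[, 16:30] <- v2[, 16:30] + 10
  m2 <- expression_matrix(v2, sprintf("g%d", 1:8), sprintf("c%d", 1:30))
  pc2 <- embed(m2, "pca")
  centroids <- rbind(colMeans(pc2[1:15, ]), colMeans(pc2[16:30, ]))
  radius <- max(sqrt(rowSums((pc2[1:15, ] - centroids[rep(1, 15), ])^2)),
                sqrt(rowSums((pc2[16:30, ] - centroids[rep(2, 15), ])^2)))
  expect_gt(sqrt(sum((centroids[1, ] - centroids[2, ])^2)), radius)
})

test_that("rank-sum marker statistics match exact enumeration", {
  # in-cluster (5,6,7) vs out (1,2,3,4): all 12 cross pairs won
  v <- rbind(c(5, 6, 7, 1, 2, 3, 4),
             c(2, 2, 2, 2, 2, 2, 2),
             c(1, 5, 2, 4, 3, 2, 5))
  m <- expression_matrix(v, c("up", "flat", "noise"), sprintf("c%d", 1:7))
  labels <- c("in", "in", "in", "out", "out", "out", "out")
  tab <- rank_markers_wilcoxon(m, labels, top_n = 3)
  up_in <- tab[tab$cluster == "in" & tab$gene_id == "up", ]
  expect_equal(up_in$statistic, 12)
  expect_equal(up_in$rank, 1)
  expect_equal(up_in$mean_in, 6)
  expect_equal(up_in$mean_out, 2.5)
  flat <- tab[tab$gene_id == "flat", ]
  expect_true(all(flat$p == 1))
  expect_true(all(flat$rank > 1))
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
})

test_that("planted expression markers rank first in their cluster", {
  sim <- make_fixture("expression_only", seed = 46)
  gem <- log_transform(sim$gem)
  tab <- rank_markers_wilcoxon(gem, sim$truth$labels, top_n = 10)
  for (t in 1:3) {
    members <- sim$gem$gene_ids[sim$truth$modules[[t]][[1]]]
    top <- tab[tab$cluster == paste0("type", t) & tab$rank <= 8, "gene_id"]
    expect_gte(length(intersect(top, members)), 6)
  }
})

test_that("null rank-sum p-values are not anti-conservative", {
  set.seed(47)
  n_genes <- 500
  v <- matrix(stats::rlnorm(n_genes * 60), n_genes, 60)
  m <- expression_matrix(v, sprintf("g%d", 1:n_genes), sprintf("c%d", 1:60))
  labels <- rep(c("a", "b"), each = 30)
  tab <- rank_markers_wilcoxon(m, labels, top_n = Inf)
  frac <- mean(tab$p[tab$cluster == "a"] < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_genes))
})

test_that("dark genes require network specificity without expression backup", {
  set.seed(48)
  n <- 40
  labels <- rep(c("a", "b"), each = n / 2)
  base <- matrix(stats::rlnorm(6 * n), 6, n)
  gem <- expression_matrix(base, sprintf("g%d", 1:6), sprintf("c%d", 1:n))
  # gene 1: important only in cluster a; gene 2: expression marker for a
  imp <- matrix(0.15, 6, n)
  imp[1, labels == "a"] <- 2.2
  imp[1, labels == "b"] <- 0.3
  imp[2, ] <- 0.8
  gim <- importance_matrix(imp, gem$gene_ids, gem$cell_ids)
  gem$values[2, labels == "a"] <- gem$values[2, labels == "a"] * 50
  dark <- find_dark_genes(gim, gem, labels)
  expect_true(any(dark$gene_id == "g1" & dark$cluster == "a"))
  expect_false(any(dark$gene_id == "g2"))
  # uniformly expressed, uniformly important genes are never dark
  expect_false(any(dark$gene_id == "g3"))
})

test_that("marker subnetworks aggregate edges by presence and mean weight", {
  set.seed(49)
  gem <- random_log_gem(6, 40, zero_frac = 0)
  cfg <- girnet_config(window_fraction = 0.25, alpha_edge = 0.2)
  wnets <- build_weighted_networks(gem, cfg)
  labels <- rep(c("x", "y"), each = 20)
  genes <- gem$gene_ids[1:4]
  # single-cell cluster equals that cell's induced subgraph
  solo <- c("x", rep("y", 39))
  g1 <- extract_marker_subnetwork(wnets, genes, gem$gene_ids, solo, "x")
  own <- wnets[[1]]$base$edges
  own <- own[own[, 1] %in% 1:4 & own[, 2] %in% 1:4, , drop = FALSE]
  expect_equal(igraph::gsize(g1), nrow(own))
  expect_error(extract_marker_subnetwork(wnets, genes, gem$gene_ids, solo, "zz"),
               "empty cluster")
  # presence threshold semantics on a hand-built collection
  mk_wnet <- function(has_edge) {
    edges <- if (has_edge) cbind(i = 1L, j = 2L) else
      matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
    net <- structure(list(cell_id = "c", nodes = 1:2, edges = edges,
                          n_genes = 2L), class = "CellNetwork")
    weight_network(net, c(1, 1))
  }
  coll <- lapply(c(TRUE, TRUE, FALSE, FALSE, FALSE), mk_wnet)
  g2 <- extract_marker_subnetwork(coll, c("gA", "gB"), c("gA", "gB"),
                                  rep("only", 5), "only")
  expect_equal(igraph::gsize(g2), 0)   # present in 40% < 50%
  coll3 <- lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE), mk_wnet)
  g3 <- extract_marker_subnetwork(coll3, c("gA", "gB"), c("gA", "gB"),
                                  rep("only", 5), "only")
  expect_equal(igraph::gsize(g3), 1)
  expect_equal(igraph::E(g3)$weight, 1)
})

test_that("each cluster's aggregate subnetwork contains its own module only", {
  sim <- make_fixture("network_only", seed = 50)
  gem <- log_transform(sim$gem)
  sub <- gem
  keep_cells <- seq(1, 500, by = 2)      # thin for speed
  sub <- expression_matrix(gem$values[, keep_cells], gem$gene_ids,
                           gem$cell_ids[keep_cells], stage = "raw")
  sub$stage <- "log"
  labels <- sim$truth$labels[keep_cells]
  wnets <- build_weighted_networks(sub)
  mod1 <- sub$gene_ids[sim$truth$modules$type1[[1]]]
  mod2 <- sub$gene_ids[sim$truth$modules$type2[[1]]]
  genes <- c(mod1, mod2)
  g_t1 <- extract_marker_subnetwork(wnets, genes, sub$gene_ids, labels, "type1")
  ends1 <- igraph::as_edgelist(g_t1)
  expect_gt(sum(ends1[, 1] %in% mod1 & ends1[, 2] %in% mod1), 0)
  expect_identical(sum(ends1[, 1] %in% mod2 & ends1[, 2] %in% mod2), 0L)
  g_t2 <- extract_marker_subnetwork(wnets, genes, sub$gene_ids, labels, "type2")
  ends2 <- igraph::as_edgelist(g_t2)
  expect_gt(sum(ends2[, 1] %in% mod2 & ends2[, 2] %in% mod2), 0)
  expect_identical(sum(ends2[, 1] %in% mod1 & ends2[, 2] %in% mod1), 0L)
})
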