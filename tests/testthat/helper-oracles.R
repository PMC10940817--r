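# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route (per-pair loops, dense linear algebra,
# exhaustive pair counting) so they share no code with the shipped paths.

# Literal per-pair network construction: neighbourhoods, independence index
# and edge test applied pair by pair.
naive_cell_network <- function(gem, k, window_fraction = 0.1, alpha = 0.01) {
  v <- gem$values
  nodes <- which(v[, k] > 0)
  edges <- matrix(integer(0), ncol = 2)
  if (length(nodes) >= 2) {
    n_C <- ncol(v)
    nb <- lapply(nodes, function(g) neighborhood(v[g, ], k, window_fraction))
    names(nb) <- as.character(nodes)
    for (a in seq_along(nodes)) {
      for (b in seq_along(nodes)) {
        if (a < b) {
          ni <- nb[[a]]; nj <- nb[[b]]
          rho <- independence_index(length(intersect(ni, nj)),
                                    length(ni), length(nj), n_C)
          if (edge_test(rho, length(ni), length(nj), n_C, alpha))
            edges <- rbind(edges, c(nodes[a], nodes[b]))
        }
      }
    }
  }
  edges
}

# Dense linear-solve fixed point of the degree-normalised walk:
# (I - d * A %*% diag(1/N_j)) %*% PR = (1 - d) * 1.
solve_pagerank_unweighted <- function(adj, damping = 0.85) {
  n <- nrow(adj)
  deg <- colSums(adj)
  M <- adj %*% diag(ifelse(deg > 0, 1 / deg, 0), n)
  solve(diag(n) - damping * M, rep(1 - damping, n))
}

# Dense fixed point of the expression-weighted walk. W[i, j] is the
# probability of stepping from j to its neighbour i, proportional to E_i.
solve_pagerank_weighted <- function(adj, expr, damping = 0.85) {
  n <- nrow(adj)
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    nbrs <- which(adj[, j] > 0)
    if (length(nbrs)) W[nbrs, j] <- expr[nbrs] / sum(expr[nbrs])
  }
  solve(diag(n) - damping * W, rep(1 - damping, n))
}

# Brute-force adjusted Rand index by counting the four pair categories.
ari_paircount <- function(a, b) {
  n <- length(a)
  s_a <- s_b <- s_ab <- s_none <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ta <- a[i] == a[j]; tb <- b[i] == b[j]
      if (ta && tb) s_ab <- s_ab + 1
      else if (ta) s_a <- s_a + 1
      else if (tb) s_b <- s_b + 1
      else s_none <- s_none + 1
    }
  }
  num <- 2 * (s_ab * s_none - s_a * s_b)
  den <- (s_ab + s_a) * (s_a + s_none) + (s_ab + s_b) * (s_b + s_none)
  if (den == 0) return(as.numeric(s_a == 0 && s_b == 0))
  num / den
}

# Random undirected graph as a CellNetwork plus matching adjacency matrix.
random_graph <- function(n_nodes, p_edge = 0.35) {
  adj <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1
    }
  }
  hits <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  net <- structure(
    list(cell_id = "synthetic", nodes = seq_len(n_nodes),
         edges = cbind(i = hits[, 1], j = hits[, 2]),
         n_genes = n_nodes),
    class = "CellNetwork"
  )
  list(net = net, adj = adj)
}

# Small random expression matrix at the log stage.
random_log_gem <- function(n_genes, n_cells, zero_frac = 0.2) {
  v <- matrix(stats::rlnorm(n_genes * n_cells), n_genes, n_cells)
  v[matrix(stats::runif(n_genes * n_cells) < zero_frac, n_genes, n_cells)] <- 0
  m <- expression_matrix(v, sprintf("g%02d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_cells)), stage = "raw")
  log_transform(m)
}
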