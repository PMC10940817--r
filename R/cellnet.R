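#' Expression neighbourhood of a cell for one gene
#'
#' The network construction compares, for each gene, which cells express it
#' at a level close to the focal cell. "Close" is made precise as the
#' `n = round(window_fraction * n_C)` cells (the focal cell `k` included)
#' whose expression of this gene is nearest to its value in cell `k` by
#' absolute difference. Ties are broken first by smaller `|cell index - k|`
#' and then by smaller cell index, making the window a deterministic
#' function of its inputs.
#'
#' @param expr Numeric vector: the gene's expression across all cells.
#' @param k Focal cell index (1-based).
#' @param window_fraction Fraction of cells in the window, in (0, 1].
#' @return Sorted integer vector of exactly `n` cell indices.
#' @export
neighborhood <- function(expr, k, window_fraction = 0.1) {
  n_C <- length(expr)
  stopifnot(k >= 1, k <= n_C, window_fraction > 0, window_fraction <= 1)
  n <- round(window_fraction * n_C)
  if (n < 1) stop("window of size ", n, " (need at least 1 cell)")
  idx <- seq_len(n_C)
  ord <- order(abs(expr - expr[k]), abs(idx - k), idx)
  sort(ord[seq_len(n)])
}

#' Independence index of a gene pair around one cell
#'
#' Compares the joint neighbourhood frequency of two genes with the product
#' of their marginal frequencies:
#' `rho = n_ij/n_C - (n_i/n_C) * (n_j/n_C)`.
#' A positive value means the two genes' expression neighbourhoods around
#' the focal cell overlap more than independence would predict. The value
#' always lies in \[-1, 1\].
#'
#' @param n_ij Number of cells in both genes' neighbourhoods.
#' @param n_i,n_j Neighbourhood sizes of each gene.
#' @param n_C Total number of cells.
#' @return The independence index (vectorised over its arguments).
#' @export
independence_index <- function(n_ij, n_i, n_j, n_C) {
  if (any(n_C <= 0)) stop("n_C must be positive")
  if (any(n_ij < 0 | n_ij > pmin(n_i, n_j) | pmax(n_i, n_j) > n_C))
    stop("counts must satisfy 0 <= n_ij <= min(n_i, n_j) <= n_C")
  n_ij / n_C - (n_i / n_C) * (n_j / n_C)
}

#' One-sided normal test for an edge
#'
#' Under independence the neighbourhood overlap of two genes behaves like
#' the intersection of two fixed-size random subsets of the cells
#' (hypergeometric), so the index has null standard deviation
#' `sigma = sqrt(n_i * n_j * (n_C - n_i) * (n_C - n_j)) / (n_C^2 * sqrt(n_C - 1))`.
#' Because the overlap count is discrete and the focal cell always sits in
#' both windows, the raw index is biased slightly upward under the null; a
#' half-count continuity correction (`rho - 0.5 / n_C`) restores the
#' nominal level (verified by Monte-Carlo calibration in the test suite).
#' The corrected standardised index `z = (rho - 0.5 / n_C) / sigma` is
#' compared with the upper-tail standard-normal quantile at `alpha`; only
#' positive association creates an edge. Degenerate windows (`n_i` or
#' `n_j` equal to 0 or `n_C`) carry no information and never produce an
#' edge.
#'
#' @param rho Independence index (vectorised).
#' @param n_i,n_j Neighbourhood sizes.
#' @param n_C Total number of cells.
#' @param alpha One-sided significance level in (0, 1).
#' @return Logical: is the pair significantly positively associated?
#' @export
edge_test <- function(rho, n_i, n_j, n_C, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1, n_C > 1)
  sigma <- sqrt(n_i * n_j * (n_C - n_i) * (n_C - n_j)) /
    (n_C^2 * sqrt(n_C - 1))
  crit <- stats::qnorm(1 - alpha)
  z <- (rho - 0.5 / n_C) / ifelse(sigma == 0, 1, sigma)
  ifelse(sigma == 0, FALSE, z > crit)
}

#' Build one cell's gene correlation network
#'
#' Nodes are the genes expressed (value > 0) in cell `k`. For every node
#' pair the marginal and joint neighbourhood counts are computed with
#' [neighborhood()], turned into an independence index and tested with
#' [edge_test()]; significant pairs become undirected edges. The
#' computation is fully deterministic.
#'
#' Internally the pairwise overlap counts are obtained in one
#' boolean-matrix cross product rather than a per-pair loop; the two paths
#' are algebraically identical.
#'
#' @param gem An [expression_matrix()] at stage `"log"` or `"hvg"`.
#' @param k Cell index.
#' @param window_fraction Neighbourhood size as a fraction of cells.
#' @param alpha Edge-test significance level.
#' @return A `CellNetwork`: list with `cell_id`, `nodes` (gene indices
#'   expressed in the cell), `edges` (two-column matrix of gene-index
#'   pairs, `i < j`) and `n_genes`.
#' @export
build_cell_network <- function(gem, k, window_fraction = 0.1, alpha = 0.01) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (!gem$stage %in% c("log", "hvg"))
    stop("network construction expects a log or hvg stage matrix")
  v <- gem$values
  n_C <- ncol(v)
  stopifnot(k >= 1, k <= n_C)
  nodes <- unname(which(v[, k] > 0))
  net <- structure(
    list(cell_id = gem$cell_ids[k], nodes = nodes,
         edges = matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("i", "j"))),
         n_genes = nrow(v)),
    class = "CellNetwork"
  )
  if (length(nodes) < 2L) {
    girnet_log("cell %s: %d node(s), empty network", gem$cell_ids[k],
               length(nodes))
    return(net)
  }
  n <- round(window_fraction * n_C)
  if (n < 1) stop("window of size ", n, " (need at least 1 cell)")

  # membership matrix: B[g, c] = TRUE iff cell c is in the window of node g
  B <- matrix(FALSE, length(nodes), n_C)
  for (gi in seq_along(nodes)) {
    B[gi, neighborhood(v[nodes[gi], ], k, window_fraction)] <- TRUE
  }
  overlap <- tcrossprod(B * 1)          # n_ij for every node pair
  rho <- overlap / n_C - (n / n_C)^2    # windows have size n by construction
  sigma <- sqrt(n * n * (n_C - n) * (n_C - n)) / (n_C^2 * sqrt(n_C - 1))
  hit <- if (sigma == 0) {
    matrix(FALSE, nrow(rho), ncol(rho))
  } else {
    (rho - 0.5 / n_C) / sigma > stats::qnorm(1 - alpha)
  }
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  pairs <- which(hit, arr.ind = TRUE)
  net$edges <- cbind(i = nodes[pairs[, 1L]], j = nodes[pairs[, 2L]])
  if (nrow(net$edges)) {
    o <- order(net$edges[, 1L], net$edges[, 2L])
    net$edges <- net$edges[o, , drop = FALSE]
  }
  net
}

#' @export
#' @method print CellNetwork
print.CellNetwork <- function(x, ...) {
  cat(sprintf("CellNetwork '%s': %d nodes, %d edges\n",
              x$cell_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Degree of every gene (length n_genes; 0 for non-nodes).
network_degrees <- function(net) {
  deg <- integer(net$n_genes)
  if (nrow(net$edges)) {
    t <- tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = net$n_genes)
    deg <- t
  }
  deg
}

#' Weight a cell network by gene expression
#'
#' Converts the undirected correlation network into a directed weighted
#' one: the weight of gene i with respect to gene j is i's expression
#' divided by the total expression of j's neighbours,
#' `W_ij = E_i / sum_{m in L_j} E_m`,
#' so for every connected node j the weights over its neighbourhood sum
#' to one: `W_ij` is the probability that a random walker at j steps to
#' i, visiting neighbours in proportion to their expression. Expression
#' must be positive on every node (guaranteed by the node definition).
#'
#' @param net A `CellNetwork`.
#' @param expr_in_cell Numeric vector of expression values over all genes
#'   in this cell (length `net$n_genes`).
#' @return A `WeightedCellNetwork`: list with `base` (the input network)
#'   and `weights`, a sparse `n_genes x n_genes` matrix with
#'   `weights[i, j] = W_ij`.
#' @export
weight_network <- function(net, expr_in_cell) {
  stopifnot(inherits(net, "CellNetwork"),
            length(expr_in_cell) == net$n_genes)
  if (any(expr_in_cell[net$nodes] <= 0))
    stop("all network nodes must have positive expression")
  E <- expr_in_cell
  ii <- net$edges[, 1L]; jj <- net$edges[, 2L]
  # neighbour expression totals per node
  denom <- numeric(net$n_genes)
  if (length(ii)) {
    sums <- rowsum(c(E[jj], E[ii]), group = c(ii, jj))
    denom[as.integer(rownames(sums))] <- sums[, 1L]
  }
  from <- c(ii, jj); to <- c(jj, ii)
  w <- E[from] / denom[to]
  W <- Matrix::sparseMatrix(i = from, j = to, x = w,
                            dims = c(net$n_genes, net$n_genes))
  structure(list(base = net, weights = W), class = "WeightedCellNetwork")
}

#' @export
#' @method print WeightedCellNetwork
print.WeightedCellNetwork <- function(x, ...) {
  cat(sprintf("WeightedCellNetwork '%s': %d nodes, %d edges\n",
              x$base$cell_id, length(x$base$nodes), nrow(x$base$edges)))
  invisible(x)
}

#' Export a cell's weighted edges as a table
#'
#' One row per undirected edge with the independence statistics recomputed
#' and both directed weights; suitable for writing as TSV.
#'
#' @param gem The expression matrix the network was built from.
#' @param wnet A `WeightedCellNetwork` for one of its cells.
#' @param window_fraction,alpha The construction parameters (used to
#'   recompute rho and z).
#' @return A data frame with columns `cell_id`, `gene_i`, `gene_j`, `rho`,
#'   `z`, `W_ij`, `W_ji`.
#' @export
edge_table <- function(gem, wnet, window_fraction = 0.1, alpha = 0.01) {
  net <- wnet$base
  k <- match(net$cell_id, gem$cell_ids)
  v <- gem$values
  n_C <- ncol(v)
  n <- round(window_fraction * n_C)
  sigma <- sqrt(n * n * (n_C - n) * (n_C - n)) / (n_C^2 * sqrt(n_C - 1))
  if (!nrow(net$edges)) {
    return(data.frame(cell_id = character(0), gene_i = character(0),
                      gene_j = character(0), rho = numeric(0), z = numeric(0),
                      W_ij = numeric(0), W_ji = numeric(0)))
  }
  rho <- apply(net$edges, 1L, function(e) {
    ni <- neighborhood(v[e[1L], ], k, window_fraction)
    nj <- neighborhood(v[e[2L], ], k, window_fraction)
    independence_index(length(intersect(ni, nj)), length(ni), length(nj), n_C)
  })
  data.frame(
    cell_id = net$cell_id,
    gene_i = gem$gene_ids[net$edges[, 1L]],
    gene_j = gem$gene_ids[net$edges[, 2L]],
    rho = rho,
    z = (rho - 0.5 / n_C) / sigma,
    W_ij = wnet$weights[net$edges],
    W_ji = wnet$weights[net$edges[, c(2L, 1L), drop = FALSE]]
  )
}
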