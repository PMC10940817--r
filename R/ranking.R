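#' PageRank on an unweighted cell network
#'
#' Synchronous (Jacobi) iteration of
#' `PR_i <- (1 - d) + d * sum_{j in L_i} PR_j / N_j`
#' from the flat start `PR = 1`, where `L_i` are i's neighbours and `N_j`
#' is j's degree. The additive `(1 - d)` constant is used as printed in the
#' classic formulation, so scores do not sum to one and isolated nodes sit
#' exactly at `1 - d`. Iteration stops when the max-norm change drops below
#' `tol`; with `d < 1` the map is a contraction, so the fixed point is
#' unique and the result deterministic.
#'
#' @param net A `CellNetwork` from [build_cell_network()].
#' @param damping Damping factor d in (0, 1).
#' @param tol Max-norm convergence tolerance.
#' @param max_iter Iteration cap; on hitting it the current vector is
#'   returned with attribute `converged = FALSE` and a warning.
#' @return Numeric vector of scores over `net$nodes` (names = gene index),
#'   with attributes `converged` and `iterations`.
#' @export
pagerank_unweighted <- function(net, damping = 0.85, tol = 1e-6,
                                max_iter = 100) {
  stopifnot(inherits(net, "CellNetwork"),
            damping > 0, damping < 1, tol > 0, max_iter >= 1)
  nn <- length(net$nodes)
  if (nn == 0L)
    return(structure(numeric(0), converged = TRUE, iterations = 0L))
  local <- match(net$edges, net$nodes)
  dim(local) <- dim(net$edges)
  from <- c(local[, 1L], local[, 2L])
  to <- c(local[, 2L], local[, 1L])
  A <- Matrix::sparseMatrix(i = from, j = to, x = rep(1, length(from)),
                            dims = c(nn, nn))
  deg <- Matrix::colSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  .pagerank_iterate(function(pr) as.vector(A %*% (pr * inv_deg)),
                    nn, damping, tol, max_iter, net$nodes)
}

#' PageRank on a weighted cell network
#'
#' As [pagerank_unweighted()] but with the expression-weighted update
#' `PR_i <- (1 - d) + d * sum_{j in L_i} PR_j * W_ij`,
#' where `W_ij = E_i / sum_{m in L_j} E_m` is the probability that the
#' walker at gene j steps to its neighbour i (neighbours are visited in
#' proportion to their expression; see [weight_network()]). Each
#' connected node's outgoing transition probabilities sum to one, so the
#' walk conserves mass exactly as the degree-normalised walk does, and
#' with equal expressions on all nodes it reduces to it identically.
#'
#' @param wnet A `WeightedCellNetwork`.
#' @inheritParams pagerank_unweighted
#' @return Numeric vector of scores over the base network's nodes, with
#'   attributes `converged` and `iterations`.
#' @export
pagerank_weighted <- function(wnet, damping = 0.85, tol = 1e-6,
                              max_iter = 100) {
  stopifnot(inherits(wnet, "WeightedCellNetwork"),
            damping > 0, damping < 1, tol > 0, max_iter >= 1)
  net <- wnet$base
  nn <- length(net$nodes)
  if (nn == 0L)
    return(structure(numeric(0), converged = TRUE, iterations = 0L))
  # M[i, j] = W_ij = P(walker at j steps to i), restricted to nodes
  M <- wnet$weights[net$nodes, net$nodes, drop = FALSE]
  .pagerank_iterate(function(pr) as.vector(M %*% pr),
                    nn, damping, tol, max_iter, net$nodes)
}

.pagerank_iterate <- function(spread, nn, damping, tol, max_iter, nodes) {
  pr <- rep(1, nn)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pr_new <- (1 - damping) + damping * spread(pr)
    delta <- max(abs(pr_new - pr))
    pr <- pr_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("PageRank did not converge in %d iterations", max_iter))
  structure(stats::setNames(pr, nodes),
            converged = converged, iterations = iter)
}

#' Build the gene importance matrix
#'
#' Runs the full per-cell chain for every cell: [build_cell_network()],
#' [weight_network()] (skipped when `cfg$weighted` is `FALSE`, which
#' reproduces the plain degree-normalised walk) and the PageRank fixed
#' point. Column k of the result holds cell k's node scores; genes
#' unexpressed in a cell receive exactly `1 - damping`, so the output has
#' the same genes x cells shape and identifiers as the input.
#'
#' @param gem An [expression_matrix()] at stage `"log"` or `"hvg"`.
#' @param cfg A [girnet_config()].
#' @return An [importance_matrix()].
#' @export
build_gim <- function(gem, cfg = girnet_config()) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  t0 <- Sys.time()
  d <- cfg$damping
  out <- matrix(1 - d, nrow(gem$values), ncol(gem$values))
  for (k in seq_len(ncol(gem$values))) {
    net <- build_cell_network(gem, k, cfg$window_fraction, cfg$alpha_edge)
    pr <- if (isTRUE(cfg$weighted)) {
      pagerank_weighted(weight_network(net, gem$values[, k]),
                        d, cfg$pr_tol, cfg$pr_max_iter)
    } else {
      pagerank_unweighted(net, d, cfg$pr_tol, cfg$pr_max_iter)
    }
    out[net$nodes, k] <- pr
  }
  girnet_log("gim: %d x %d in %.2fs", nrow(out), ncol(out),
             as.numeric(Sys.time() - t0, units = "secs"))
  importance_matrix(out, gem$gene_ids, gem$cell_ids, damping = d)
}

#' Build the network degree matrix
#'
#' Column k holds every gene's degree in cell k's unweighted correlation
#' network (0 for unexpressed genes). Shape and identifiers match the
#' input, making the result directly comparable with the importance
#' matrix.
#'
#' @inheritParams build_gim
#' @return A [degree_matrix()].
#' @export
build_ndm <- function(gem, cfg = girnet_config()) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  out <- matrix(0L, nrow(gem$values), ncol(gem$values))
  for (k in seq_len(ncol(gem$values))) {
    net <- build_cell_network(gem, k, cfg$window_fraction, cfg$alpha_edge)
    out[, k] <- network_degrees(net)
  }
  degree_matrix(out, gem$gene_ids, gem$cell_ids)
}

#' Build every cell's weighted network
#'
#' Used by the marker-subnetwork analysis, which aggregates edges over the
#' cells of a cluster.
#'
#' @inheritParams build_gim
#' @return List of `WeightedCellNetwork`, one per cell, in cell order.
#' @export
build_weighted_networks <- function(gem, cfg = girnet_config()) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  lapply(seq_len(ncol(gem$values)), function(k) {
    net <- build_cell_network(gem, k, cfg$window_fraction, cfg$alpha_edge)
    weight_network(net, gem$values[, k])
  })
}
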