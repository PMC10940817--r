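#' Filter rarely expressed genes and outlier cells
#'
#' Genes expressed (value > 0) in fewer than `min_cells_per_gene` cells are
#' removed first; then cells whose total expression (over the surviving
#' genes) falls strictly below the `lower_q` quantile or strictly above the
#' `upper_q` quantile of the per-cell totals are removed. Survivor order is
#' preserved.
#'
#' @param m An [expression_matrix()] at stage `"raw"`.
#' @param min_cells_per_gene Minimum number of cells a gene must be
#'   expressed in.
#' @param lower_q,upper_q Quantile bounds on per-cell total expression,
#'   `0 <= lower_q < upper_q <= 1`.
#' @return The filtered matrix at stage `"filtered"`.
#' @export
filter_cells_genes <- function(m, min_cells_per_gene = 3,
                               lower_q = 0.01, upper_q = 0.99) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$stage != "raw") stop("filter_cells_genes expects a raw matrix")
  stopifnot(lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  t0 <- Sys.time()

  keep_genes <- rowSums(m$values > 0) >= min_cells_per_gene
  if (!any(keep_genes))
    stop(sprintf("gene filter removed all %d genes (min_cells_per_gene=%d)",
                 nrow(m$values), min_cells_per_gene))
  v <- m$values[keep_genes, , drop = FALSE]

  totals <- colSums(v)
  bounds <- stats::quantile(totals, c(lower_q, upper_q), names = FALSE)
  keep_cells <- totals >= bounds[1L] & totals <= bounds[2L]
  if (!any(keep_cells))
    stop(sprintf("cell filter removed all %d cells (quantiles %.3g-%.3g)",
                 ncol(v), lower_q, upper_q))

  out <- expression_matrix(v[, keep_cells, drop = FALSE],
                           m$gene_ids[keep_genes],
                           m$cell_ids[keep_cells], stage = "raw")
  out <- advance_stage(out, "filtered")
  girnet_log("filter: %d x %d -> %d x %d (%.2fs)",
             nrow(m$values), ncol(m$values),
             nrow(out$values), ncol(out$values),
             as.numeric(Sys.time() - t0, units = "secs"))
  out
}

#' Log-transform expression values
#'
#' Replaces every entry E by log(E + 1) (natural log), shrinking the
#' dynamic range of the data before network construction.
#'
#' @param m An [expression_matrix()] at stage `"raw"` or `"filtered"`.
#' @return The transformed matrix at stage `"log"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!m$stage %in% c("raw", "filtered"))
    stop("log_transform expects a raw or filtered matrix, got stage ", m$stage)
  out <- m
  out$values <- log1p(m$values)
  advance_stage(out, "log")
}

#' Select highly variable genes
#'
#' Keeps the `n_hvg` genes with the largest variance of log expression
#' across cells (all genes if fewer exist). Ties are broken by original
#' gene order and the selected genes keep their relative order.
#'
#' @param m An [expression_matrix()] at stage `"log"`.
#' @param n_hvg Number of genes to retain (>= 2).
#' @return The reduced matrix at stage `"hvg"`.
#' @export
select_hvg <- function(m, n_hvg = 2000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$stage != "log") stop("select_hvg expects a log-stage matrix")
  stopifnot(n_hvg >= 1)
  v <- m$values
  ng <- nrow(v)
  if (n_hvg >= ng) {
    girnet_log("hvg: keeping all %d genes", ng)
    return(advance_stage(m, "hvg"))
  }
  mu <- rowMeans(v)
  vars <- rowSums((v - mu)^2) / (ncol(v) - 1L)
  keep <- sort(order(-vars, seq_len(ng))[seq_len(n_hvg)])
  out <- expression_matrix(v[keep, , drop = FALSE],
                           m$gene_ids[keep], m$cell_ids, stage = "raw")
  out <- advance_stage(out, "hvg")
  girnet_log("hvg: %d -> %d genes", ng, n_hvg)
  out
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: [filter_cells_genes()], [log_transform()],
#' [select_hvg()] with thresholds taken from a [girnet_config()].
#'
#' @param m A raw [expression_matrix()].
#' @param cfg A [girnet_config()].
#' @return The preprocessed matrix at stage `"hvg"`.
#' @export
preprocess <- function(m, cfg = girnet_config()) {
  m <- filter_cells_genes(m, cfg$min_cells_per_gene,
                          cfg$total_counts_lower_quantile,
                          cfg$total_counts_upper_quantile)
  m <- log_transform(m)
  select_hvg(m, cfg$n_hvg)
}
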