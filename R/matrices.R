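#' Gene-by-cell expression matrix container
#'
#' The central data structure of the pipeline: a dense non-negative matrix of
#' expression values with genes in rows and cells in columns, plus unique
#' gene and cell identifiers and a processing `stage` marker. The stage can
#' only move forward along `raw -> filtered -> log -> hvg`, which prevents,
#' for example, log-transforming twice or running network construction on
#' untransformed counts by accident.
#'
#' @param values Numeric matrix, genes x cells. No negative, `NA` or
#'   infinite entries are allowed.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column.
#' @param stage Processing stage, one of `"raw"`, `"filtered"`, `"log"`,
#'   `"hvg"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, stage = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  stage <- match.arg(stage, .gem_stages)
  m <- structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         stage = stage),
    class = "ExpressionMatrix"
  )
  validate_expression_matrix(m)
  dimnames(m$values) <- list(gene_ids, cell_ids)
  m
}

.gem_stages <- c("raw", "filtered", "log", "hvg")

validate_expression_matrix <- function(m) {
  v <- m$values
  if (!is.matrix(v) || !is.numeric(v))
    stop("values must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v)))
    stop("values contain NA/NaN/Inf entries")
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at gene '%s', cell '%s'",
                 m$gene_ids[bad[1L]], m$cell_ids[bad[2L]]))
  }
  if (length(m$gene_ids) != nrow(v))
    stop("gene_ids length does not match number of rows")
  if (length(m$cell_ids) != ncol(v))
    stop("cell_ids length does not match number of columns")
  if (anyDuplicated(m$gene_ids))
    stop(sprintf("duplicate gene id: '%s'",
                 m$gene_ids[anyDuplicated(m$gene_ids)]))
  if (anyDuplicated(m$cell_ids))
    stop(sprintf("duplicate cell id: '%s'",
                 m$cell_ids[anyDuplicated(m$cell_ids)]))
  if (!m$stage %in% .gem_stages)
    stop("unknown stage: ", m$stage)
  invisible(m)
}

# Enforce the forward-only stage contract raw -> filtered -> log -> hvg.
advance_stage <- function(m, to) {
  from_i <- match(m$stage, .gem_stages)
  to_i <- match(to, .gem_stages)
  if (is.na(to_i)) stop("unknown stage: ", to)
  if (to_i < from_i)
    stop(sprintf("stage cannot move backwards (%s -> %s)", m$stage, to))
  m$stage <- to
  m
}

#' @export
#' @method print ExpressionMatrix
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene importance matrix (per-cell PageRank scores)
#'
#' Same shape as the source expression matrix; entry `[i, k]` is the
#' PageRank score of gene `i` in the network of cell `k`. Genes unexpressed
#' in a cell carry the baseline score `1 - damping`.
#'
#' @param values Numeric matrix of PageRank scores, genes x cells.
#' @param gene_ids,cell_ids Identifiers aligned with the source matrix.
#' @param damping Damping factor used for the random walk.
#' @return An object of class `ImportanceMatrix`.
#' @export
importance_matrix <- function(values, gene_ids, cell_ids, damping = 0.85) {
  values <- as.matrix(values)
  if (any(values < (1 - damping) - 1e-9))
    stop("importance scores below the (1 - damping) floor")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids), damping = damping),
    class = "ImportanceMatrix"
  )
}

#' @export
#' @method print ImportanceMatrix
print.ImportanceMatrix <- function(x, ...) {
  cat(sprintf("ImportanceMatrix: %d genes x %d cells [damping: %g]\n",
              nrow(x$values), ncol(x$values), x$damping))
  invisible(x)
}

#' Network degree matrix
#'
#' Same shape as the source expression matrix; entry `[i, k]` is the degree
#' of gene `i` in the (unweighted) correlation network of cell `k`, and 0
#' for genes unexpressed in that cell.
#'
#' @param values Non-negative integer matrix of node degrees, genes x cells.
#' @param gene_ids,cell_ids Identifiers aligned with the source matrix.
#' @return An object of class `DegreeMatrix`.
#' @export
degree_matrix <- function(values, gene_ids, cell_ids) {
  values <- as.matrix(values)
  if (any(values < 0) || any(values != round(values)))
    stop("degrees must be non-negative integers")
  if (any(values >= length(gene_ids)))
    stop("degree exceeds the number of potential neighbours")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids)),
    class = "DegreeMatrix"
  )
}

#' @export
#' @method print DegreeMatrix
print.DegreeMatrix <- function(x, ...) {
  cat(sprintf("DegreeMatrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Extract the numeric genes x cells matrix from any pipeline container (or
# pass a plain matrix through).
matrix_values <- function(m) {
  if (is.matrix(m)) return(m)
  if (is.list(m) && is.matrix(m$values)) return(m$values)
  stop("cannot extract a genes x cells matrix from object of class ",
       paste(class(m), collapse = "/"))
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Values mirror
#' the construction described in the package vignette: a fixed expression
#' neighbourhood of 10% of cells, a per-pair significance of 0.01 for the
#' independence-index edge test, and a damping factor of 0.85 for the
#' random walk.
#'
#' @param min_cells_per_gene Genes expressed in fewer cells are dropped.
#' @param total_counts_lower_quantile,total_counts_upper_quantile Cells with
#'   total expression outside these quantiles of the per-cell totals are
#'   dropped.
#' @param n_hvg Number of highly variable genes retained.
#' @param window_fraction Fraction of cells in each gene's expression
#'   neighbourhood.
#' @param alpha_edge Per-pair significance level of the edge test.
#' @param damping PageRank damping factor d.
#' @param pr_tol Max-norm convergence tolerance of the PageRank iteration.
#' @param pr_max_iter Iteration cap for the PageRank fixed point.
#' @param weighted Use expression-weighted PageRank (`TRUE`) or the plain
#'   degree-normalised walk (`FALSE`).
#' @return A list of class `girnet_config`.
#' @export
girnet_config <- function(min_cells_per_gene = 3,
                          total_counts_lower_quantile = 0.01,
                          total_counts_upper_quantile = 0.99,
                          n_hvg = 2000,
                          window_fraction = 0.1,
                          alpha_edge = 0.01,
                          damping = 0.85,
                          pr_tol = 1e-6,
                          pr_max_iter = 100,
                          weighted = TRUE) {
  cfg <- list(
    min_cells_per_gene = min_cells_per_gene,
    total_counts_lower_quantile = total_counts_lower_quantile,
    total_counts_upper_quantile = total_counts_upper_quantile,
    n_hvg = n_hvg,
    window_fraction = window_fraction,
    alpha_edge = alpha_edge,
    damping = damping,
    pr_tol = pr_tol,
    pr_max_iter = pr_max_iter,
    weighted = weighted
  )
  stopifnot(cfg$window_fraction > 0, cfg$window_fraction <= 1,
            cfg$alpha_edge > 0, cfg$alpha_edge < 1,
            cfg$damping > 0, cfg$damping < 1,
            cfg$pr_tol > 0, cfg$pr_max_iter >= 1)
  class(cfg) <- "girnet_config"
  cfg
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' an error; values are coerced to the type of the default.
#'
#' @param path Path to the configuration file.
#' @return A `girnet_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- girnet_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.logical(cfg[[key]])) {
      toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else {
      as.numeric(val)
    }
  }
  do.call(girnet_config, unclass(cfg))
}

girnet_log <- function(fmt, ..., verbose = getOption("girnet.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
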