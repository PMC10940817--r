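#' Read a genes x cells matrix from disk
#'
#' Two on-disk layouts are supported: the 10x-style MatrixMarket triplet
#' (`format = "mtx_dir"`: a directory holding `matrix.mtx` plus `genes.tsv`
#' and `barcodes.tsv` sidecars) and a dense delimited table
#' (`format = "dense_table"`: first column gene ids, header row cell ids;
#' comma- or tab-separated by file extension).
#'
#' MTX files may store either genes or cells in rows; orientation is
#' detected from the sidecar lengths and normalised to genes x cells. A
#' square matrix with equally long sidecars is ambiguous and rejected.
#'
#' @param path Directory (for `mtx_dir`) or file (for `dense_table`).
#' @param format One of `"mtx_dir"`, `"dense_table"`.
#' @return An [expression_matrix()] with `stage = "raw"`.
#' @export
read_matrix <- function(path, format = c("mtx_dir", "dense_table")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    .read_mtx_dir(path)
  } else {
    .read_dense_table(path)
  }
}

.sidecar_path <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing sidecar file in ", dir, ": expected one of ",
       paste(candidates, collapse = ", "))
}

.read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  mtx <- .sidecar_path(path, c("matrix.mtx", "matrix.mtx.gz"))
  genes_f <- .sidecar_path(path, c("genes.tsv", "features.tsv"))
  cells_f <- .sidecar_path(path, "barcodes.tsv")
  gene_tab <- utils::read.delim(genes_f, header = FALSE,
                                colClasses = "character")
  gene_ids <- gene_tab[[1L]]
  cell_ids <- utils::read.delim(cells_f, header = FALSE,
                                colClasses = "character")[[1L]]
  m <- as.matrix(Matrix::readMM(mtx))
  ng <- length(gene_ids); nc <- length(cell_ids)
  if (nrow(m) == ng && ncol(m) == nc) {
    if (ng == nc)
      stop("square matrix with equally long sidecars: orientation ambiguous")
  } else if (nrow(m) == nc && ncol(m) == ng) {
    m <- t(m)
  } else {
    stop(sprintf(
      "matrix dims %d x %d match neither sidecar orientation (%d genes, %d cells)",
      nrow(m), ncol(m), ng, nc))
  }
  expression_matrix(m, gene_ids, cell_ids, stage = "raw")
}

.read_dense_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_matrix(vals, gene_ids, colnames(tab)[-1L], stage = "raw")
}

#' Write a genes x cells matrix to disk
#'
#' Accepts any of the pipeline's matrix containers ([expression_matrix()],
#' [importance_matrix()], [degree_matrix()]). The MTX writer emits full
#' double precision so that a write/read round trip preserves values to
#' better than 1e-12.
#'
#' @param m Matrix container to write.
#' @param path Target directory (`mtx_dir`) or file (`dense_table`).
#' @param format One of `"mtx_dir"`, `"dense_table"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("mtx_dir", "dense_table")) {
  format <- match.arg(format)
  vals <- matrix_values(m)
  gene_ids <- if (is.null(m$gene_ids)) rownames(vals) else m$gene_ids
  cell_ids <- if (is.null(m$cell_ids)) colnames(vals) else m$cell_ids
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    .write_mtx(vals, file.path(path, "matrix.mtx"))
    writeLines(gene_ids, file.path(path, "genes.tsv"))
    writeLines(cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(gene = gene_ids, vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", cell_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

# MatrixMarket coordinate writer with %.17g entries; Matrix::writeMM trims
# precision, which would break the 1e-12 round-trip contract.
.write_mtx <- function(vals, file) {
  nz <- which(vals != 0)
  header <- c("%%MatrixMarket matrix coordinate real general",
              sprintf("%d %d %d", nrow(vals), ncol(vals), length(nz)))
  if (length(nz)) {
    rows <- ((nz - 1L) %% nrow(vals)) + 1L
    cols <- ((nz - 1L) %/% nrow(vals)) + 1L
    body <- sprintf("%d %d %.17g", rows, cols, vals[nz])
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read per-cell labels
#'
#' Either one bare label per line (taken to be in the same order as
#' `cells`) or a two-column table `(cell_id, label)` in any order, which is
#' realigned to `cells`.
#'
#' @param path Path to the label file (TSV).
#' @param cells Character vector of cell ids the labels must align with.
#' @return Character vector of labels, one per cell, in `cells` order.
#' @export
read_labels <- function(path, cells) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) == 1L) {
    labels <- tab[[1L]]
    if (length(labels) != length(cells))
      stop(sprintf("label file has %d entries but %d cells expected",
                   length(labels), length(cells)))
    return(labels)
  }
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate cell id in label file: '", ids[anyDuplicated(ids)], "'")
  idx <- match(cells, ids)
  if (anyNA(idx))
    stop("label file is missing cell '", cells[which(is.na(idx))[1L]], "'")
  tab[[2L]][idx]
}

#' Write per-cell labels as a two-column TSV
#'
#' @param labels Character vector of labels.
#' @param cells Cell ids aligned with `labels`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, cells, path) {
  stopifnot(length(labels) == length(cells))
  utils::write.table(data.frame(cell = cells, label = labels),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
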