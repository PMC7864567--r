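#' Single-cell count matrix with per-cell metadata
#'
#' Container for a sparse gene-by-cell count matrix together with per-cell
#' metadata (mitochondrial fraction, detected genes, UMIs, doublet score,
#' cell-cycle scores, sample and cluster labels) and QC flags. Detected-gene
#' and UMI totals are always recomputed from the counts so the metadata can
#' never drift out of step with the matrix.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in rows,
#'   cells in columns; both dimnames required.
#' @param meta `data.frame` of per-cell metadata, one row per cell, in the
#'   same order as the columns of `counts`. Optional; missing columns are
#'   filled with `NA`.
#' @return An object of class `cell_matrix`: a list with elements `counts`
#'   (`dgCMatrix`), `meta` (`data.frame` keyed by `cell`), and `logcounts`
#'   (`NULL` until [normalize_log()] is called).
#' @export
cell_matrix <- function(counts, meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  n <- ncol(counts)
  if (is.null(meta)) meta <- data.frame(cell = colnames(counts))
  if (!"cell" %in% names(meta)) meta$cell <- colnames(counts)
  if (nrow(meta) != n || !identical(meta$cell, colnames(counts)))
    stop("meta must have one row per cell, in column order, keyed by 'cell'")
  meta$n_umis <- Matrix::colSums(counts)
  meta$n_genes_detected <- Matrix::colSums(counts > 0)
  for (col in c("mito_fraction", "doublet_score", "s_score", "g2m_score",
                "sample", "cluster")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  if (!"qc_pass" %in% names(meta)) meta$qc_pass <- TRUE
  if (!"qc_reasons" %in% names(meta)) meta$qc_reasons <- ""
  rownames(meta) <- meta$cell
  structure(list(counts = counts, meta = meta, logcounts = NULL),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%d passing QC)\n",
              nrow(x$counts), ncol(x$counts), sum(x$meta$qc_pass)))
  if (!all(is.na(x$meta$cluster)))
    cat(sprintf("  clusters: %s\n",
                paste(sort(unique(as.character(x$meta$cluster))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cells
#'
#' @param x a [cell_matrix()].
#' @param cells character vector of cell ids or logical/integer index over
#'   columns.
#' @return A `cell_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(is(x, "cell_matrix"))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  if (anyNA(cells)) stop("unknown cell id in subset")
  out <- x
  out$counts <- x$counts[, cells, drop = FALSE]
  out$meta <- x$meta[cells, , drop = FALSE]
  if (!is.null(x$logcounts)) out$logcounts <- x$logcounts[, cells, drop = FALSE]
  out
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to a fixed total count and applies a natural-log
#' transform with a pseudocount of one:
#' `value_g = ln(1 + scale * count_g / total_counts_cell)`.
#' Zeros remain zero, so sparsity is preserved; ranking of genes within a
#' cell is unchanged because the map is monotone per cell.
#'
#' @param x a [cell_matrix()].
#' @param scale_factor target total per cell (default 10,000).
#' @return `x` with a `logcounts` sparse matrix filled in.
#' @export
normalize_log <- function(x, scale_factor = 1e4) {
  stopifnot(is(x, "cell_matrix"))
  depth <- Matrix::colSums(x$counts)
  if (any(depth == 0))
    stop("cells with zero counts cannot be normalized: ",
         paste(head(colnames(x$counts)[depth == 0]), collapse = ", "))
  lc <- x$counts %*% Matrix::Diagonal(x = scale_factor / depth)
  lc <- as(lc, "CsparseMatrix")
  lc@x <- log1p(lc@x)
  dimnames(lc) <- dimnames(x$counts)
  x$logcounts <- lc
  x
}

logcounts_or_stop <- function(x) {
  if (is.null(x$logcounts))
    stop("call normalize_log() first; log-normalized expression is required")
  x$logcounts
}

#' Cluster cells on principal components (plumbing)
#'
#' Standard-workflow clustering used where the pipeline needs cluster labels
#' (the high-resolution QC cluster rule, query cluster averaging). Runs PCA on
#' the most variable genes of the log-normalized matrix and k-means with a
#' seeded multi-start. The routine is deliberately plain: clustering internals
#' are not part of the methods this package contributes.
#'
#' @param x a [cell_matrix()] with logcounts (see [normalize_log()]).
#' @param k number of clusters.
#' @param n_hvg number of most-variable genes used for PCA.
#' @param n_pcs number of principal components.
#' @param seed RNG seed for the k-means multi-start.
#' @param label_col metadata column to write the labels into.
#' @return `x` with cluster labels in `meta[[label_col]]`.
#' @export
cluster_cells <- function(x, k, n_hvg = 500, n_pcs = 20, seed = 1,
                          label_col = "cluster") {
  lc <- logcounts_or_stop(x)
  gene_var <- rowVars_sparse(lc)
  hvg <- order(gene_var, decreasing = TRUE)[seq_len(min(n_hvg, nrow(lc)))]
  mat <- t(as.matrix(lc[hvg, , drop = FALSE]))
  n_pcs <- min(n_pcs, ncol(mat) - 1L, nrow(mat) - 1L)
  pcs <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  set.seed(seed)
  cl <- kmeans(pcs, centers = k, nstart = 10, iter.max = 50)$cluster
  x$meta[[label_col]] <- paste0("c", cl)
  x
}

rowVars_sparse <- function(m) {
  mu <- Matrix::rowMeans(m)
  Matrix::rowMeans(m^2) - mu^2
}
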