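#' Write a cell_matrix as MTX plus TSV sidecars
#'
#' Serializes the counts in MatrixMarket format with `genes.tsv`,
#' `barcodes.tsv`, and a `metadata.tsv` holding the per-cell columns
#' (including QC flags), the layout used by common single-cell toolchains.
#'
#' @param x a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cell_matrix <- function(x, dir) {
  stopifnot(is(x, "cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                            "metadata.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  writeLines(rownames(x$counts), paths[2])
  writeLines(colnames(x$counts), paths[3])
  write_tsv(x$meta, paths[4])
  invisible(paths)
}

#' Read a cell_matrix written by [write_cell_matrix()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`,
#'   and optionally `metadata.tsv`.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path))
    read.table(meta_path, header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE, comment.char = "")
  else NULL
  cell_matrix(counts, meta)
}

#' Write a data.frame as TSV with fixed formatting
#'
#' Deterministic tab-separated writer (no quoting, no row names, fixed
#' 15-significant-digit numeric formatting) so that reruns of a pipeline
#' produce byte-identical outputs.
#'
#' @param d a `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(d, path) {
  d <- as.data.frame(d)
  for (col in names(d)) {
    if (is.numeric(d[[col]]) && !is.integer(d[[col]]))
      d[[col]] <- sprintf("%.15g", d[[col]])
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Three-column (plus optional name/score) BED, 0-based half-open, matching
#' the coordinate convention used throughout the package.
#'
#' @param d `data.frame` with `chrom, start, end` and optional extra
#'   columns appended in order.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(d, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(d)))
  extra <- setdiff(names(d), c("chrom", "start", "end"))
  out <- d[, c("chrom", "start", "end", extra), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialize a reference model as a coefficient TSV
#'
#' Long-format table (gene, class, coefficient) preceded by `#`-prefixed
#' header lines carrying the intercepts, alpha, and per-class lambda, so a
#' model can be exchanged as plain text.
#'
#' @param model a [train_reference_model()] fit.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_reference_model <- function(model, path) {
  stopifnot(is(model, "reference_model"))
  hdr <- c(sprintf("# alpha\t%.15g", model$alpha),
           sprintf("# intercept\t%s\t%.15g", model$class_labels,
                   model$intercepts),
           sprintf("# lambda\t%s\t%.15g", model$class_labels, model$lambda))
  nz <- which(model$coefficients != 0, arr.ind = TRUE)
  tab <- data.frame(gene = model$gene_list[nz[, 1]],
                    class = model$class_labels[nz[, 2]],
                    coefficient = model$coefficients[nz],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$class, tab$gene), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("gene\tclass\tcoefficient", con)
  writeLines(sprintf("%s\t%s\t%.15g", tab$gene, tab$class,
                     tab$coefficient), con)
  invisible(path)
}
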