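#' QC threshold presets
#'
#' Three platform profiles govern per-cell filtering:
#' \describe{
#'   \item{adrenal}{10x fetal adrenal reference: fail cells with mitochondrial
#'     fraction above 0.30, fewer than 300 detected genes, fewer than 1000
#'     UMIs, or doublet score above 0.2; additionally fail whole
#'     high-resolution clusters in which more than 50% of cells fail
#'     individually, and exclude cycling cells (S or G2M score above 0).}
#'   \item{tumor10x}{10x tumor data: mitochondrial fraction above 0.20, fewer
#'     than 300 genes, fewer than 1000 UMIs. No doublet, cluster, or cycling
#'     rule.}
#'   \item{tumorplate}{plate-based (CEL-Seq2-like) tumor data: mitochondrial
#'     fraction above 0.20, fewer than 200 genes, fewer than 500 UMIs.}
#' }
#' All comparisons are strict: a cell at exactly the threshold passes.
#'
#' @param preset one of `"adrenal"`, `"tumor10x"`, `"tumorplate"`, or
#'   `"custom"` (all fields taken from the arguments).
#' @param max_mito_fraction,min_genes,min_umis,max_doublet_score,cluster_fail_fraction,exclude_cycling
#'   overrides for individual fields; `max_doublet_score = NA` and
#'   `cluster_fail_fraction = NA` disable those rules.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(preset = c("adrenal", "tumor10x", "tumorplate",
                                     "custom"),
                          max_mito_fraction = NULL, min_genes = NULL,
                          min_umis = NULL, max_doublet_score = NULL,
                          cluster_fail_fraction = NULL,
                          exclude_cycling = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    adrenal = list(max_mito_fraction = 0.30, min_genes = 300L,
                   min_umis = 1000L, max_doublet_score = 0.2,
                   cluster_fail_fraction = 0.5, exclude_cycling = TRUE),
    tumor10x = list(max_mito_fraction = 0.20, min_genes = 300L,
                    min_umis = 1000L, max_doublet_score = NA_real_,
                    cluster_fail_fraction = NA_real_, exclude_cycling = FALSE),
    tumorplate = list(max_mito_fraction = 0.20, min_genes = 200L,
                      min_umis = 500L, max_doublet_score = NA_real_,
                      cluster_fail_fraction = NA_real_,
                      exclude_cycling = FALSE),
    custom = list(max_mito_fraction = 1, min_genes = 0L, min_umis = 0L,
                  max_doublet_score = NA_real_,
                  cluster_fail_fraction = NA_real_, exclude_cycling = FALSE))
  for (f in names(base)) {
    v <- get(f)
    if (!is.null(v)) base[[f]] <- v
  }
  with(base, {
    if (max_mito_fraction < 0 || max_mito_fraction > 1)
      stop("max_mito_fraction must lie in [0, 1]")
    if (!is.na(cluster_fail_fraction) &&
        (cluster_fail_fraction < 0 || cluster_fail_fraction > 1))
      stop("cluster_fail_fraction must lie in [0, 1]")
    if (min_genes < 0 || min_umis < 0)
      stop("min_genes and min_umis must be non-negative")
  })
  structure(c(base, list(preset = preset)), class = "qc_thresholds")
}

add_fail <- function(meta, idx, reason) {
  meta$qc_pass[idx] <- FALSE
  meta$qc_reasons[idx] <- ifelse(
    meta$qc_reasons[idx] == "", reason,
    paste(meta$qc_reasons[idx], reason, sep = ";"))
  meta
}

#' Flag cells against per-cell QC thresholds
#'
#' Marks each cell pass/fail with the set of violated rules. Thresholds are
#' strict as stated in the presets: mitochondrial fraction must exceed the
#' maximum to fail (exactly at it passes), detected genes and UMIs must fall
#' below the minimum to fail (exactly at it passes), doublet score must
#' exceed the maximum to fail. Flags are recomputed from scratch each call,
#' so the operation is idempotent.
#'
#' @param x a [cell_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return `x` with `meta$qc_pass` and `meta$qc_reasons` set.
#' @export
flag_cells <- function(x, thresholds) {
  stopifnot(is(x, "cell_matrix"), is(thresholds, "qc_thresholds"))
  meta <- x$meta
  meta$qc_pass <- TRUE
  meta$qc_reasons <- ""
  if (anyNA(meta$mito_fraction))
    stop("mito_fraction missing for cells: ",
         paste(head(meta$cell[is.na(meta$mito_fraction)]), collapse = ", "))
  meta <- add_fail(meta, meta$mito_fraction > thresholds$max_mito_fraction,
                   "mito")
  meta <- add_fail(meta, meta$n_genes_detected < thresholds$min_genes,
                   "genes")
  meta <- add_fail(meta, meta$n_umis < thresholds$min_umis, "umis")
  if (!is.na(thresholds$max_doublet_score)) {
    if (anyNA(meta$doublet_score))
      stop("doublet_score missing for cells: ",
           paste(head(meta$cell[is.na(meta$doublet_score)]), collapse = ", "))
    meta <- add_fail(meta, meta$doublet_score > thresholds$max_doublet_score,
                     "doublet")
  }
  x$meta <- meta
  x
}

#' Fail whole clusters dominated by failing cells
#'
#' Any cell belonging to a (high-resolution) cluster in which the fraction of
#' individually failing cells strictly exceeds `cluster_fail_fraction` is
#' marked failed with reason `"cluster"`. Only individual-rule failures
#' (mito/genes/umis/doublet) count toward the fraction, so repeated
#' application does not cascade.
#'
#' @param x a [cell_matrix()] already processed by [flag_cells()].
#' @param thresholds a [qc_thresholds()] with a non-`NA`
#'   `cluster_fail_fraction`.
#' @param cluster_col metadata column holding the cluster labels.
#' @return `x` with cluster-level failures added.
#' @export
apply_cluster_rule <- function(x, thresholds, cluster_col = "cluster") {
  stopifnot(is(x, "cell_matrix"), is(thresholds, "qc_thresholds"))
  if (is.na(thresholds$cluster_fail_fraction)) return(x)
  cl <- x$meta[[cluster_col]]
  if (anyNA(cl)) stop("cells without a cluster label: ",
                      paste(head(x$meta$cell[is.na(cl)]), collapse = ", "))
  indiv_fail <- vapply(
    strsplit(x$meta$qc_reasons, ";", fixed = TRUE),
    function(r) any(r %in% c("mito", "genes", "umis", "doublet")),
    logical(1))
  frac <- tapply(indiv_fail, cl, mean)
  bad <- names(frac)[frac > thresholds$cluster_fail_fraction]
  x$meta <- add_fail(x$meta, cl %in% bad, "cluster")
  x
}

#' Exclude cycling cells
#'
#' Cells whose S-phase or G2M-phase score is strictly greater than zero are
#' flagged with reason `"cycling"`; a score of exactly zero is kept. Removing
#' them restricts a reference map to G0/G1 cells, so that clustering reflects
#' cell type rather than cell-cycle phase.
#'
#' @param x a [cell_matrix()] with `s_score` and `g2m_score` metadata.
#' @return `x` with cycling failures added.
#' @export
filter_cell_cycle <- function(x) {
  stopifnot(is(x, "cell_matrix"))
  s <- x$meta$s_score
  g <- x$meta$g2m_score
  if (anyNA(s) || anyNA(g))
    stop("s_score / g2m_score missing for cells: ",
         paste(head(x$meta$cell[is.na(s) | is.na(g)]), collapse = ", "))
  add <- s > 0 | g > 0
  x$meta <- add_fail(x$meta, add, "cycling")
  x
}

#' Run the full QC pass for a preset
#'
#' Applies [flag_cells()], then (where the preset activates them) the
#' cluster-level rule and the cell-cycle exclusion. The adrenal preset uses
#' all three stages, the two tumor presets only the per-cell stage.
#'
#' @param x a [cell_matrix()].
#' @param thresholds a [qc_thresholds()] (or preset name).
#' @param cluster_col metadata column with high-resolution cluster labels
#'   (required only when the cluster rule is active).
#' @return `x` with all QC flags set.
#' @export
apply_qc <- function(x, thresholds = qc_thresholds("adrenal"),
                     cluster_col = "cluster") {
  if (is.character(thresholds)) thresholds <- qc_thresholds(thresholds)
  x <- flag_cells(x, thresholds)
  if (!is.na(thresholds$cluster_fail_fraction))
    x <- apply_cluster_rule(x, thresholds, cluster_col)
  if (isTRUE(thresholds$exclude_cycling))
    x <- filter_cell_cycle(x)
  x
}

#' Subset to QC-passing cells
#'
#' @param x a flagged [cell_matrix()].
#' @return A `cell_matrix` with only the passing cells.
#' @export
qc_survivors <- function(x) {
  stopifnot(is(x, "cell_matrix"))
  subset_cells(x, which(x$meta$qc_pass))
}

#' QC report table
#'
#' @param x a flagged [cell_matrix()].
#' @return A `data.frame` with cell, pass/fail, and reason codes.
#' @export
qc_report <- function(x) {
  stopifnot(is(x, "cell_matrix"))
  data.frame(cell = x$meta$cell, qc_pass = x$meta$qc_pass,
             qc_reasons = x$meta$qc_reasons, stringsAsFactors = FALSE)
}
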