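#' tf-idf marker statistics with hypergeometric tests
#'
#' For every gene and cluster, computes the in-cluster expressing fraction
#' (`tf`, a gene is "expressed" when its count is > 0), the global
#' expressing fraction (`global_rate`), and the tf-idf statistic
#' `tf * ln(1 / global_rate)` (0 when the gene is expressed everywhere).
#' The natural logarithm makes the cutoff identity exact: a gene passes
#' cutoff t precisely when `global_rate < exp(-t / tf)`. Significance is an
#' upper-tail hypergeometric test of drawing the cluster's expressing cells
#' from the global pool of expressing cells, Benjamini-Hochberg adjusted
#' over all gene-cluster pairs.
#'
#' @param x a [cell_matrix()].
#' @param clusters cluster label per cell (defaults to `meta$cluster`).
#' @param tfidf_cutoff keep rows with tf-idf strictly above this.
#' @param p_cutoff keep rows with adjusted p strictly below this.
#' @param return_all return the full gene-by-cluster table instead of only
#'   rows passing both cutoffs.
#' @return `data.frame` with columns `gene, cluster, tf, global_rate,
#'   tfidf, p_raw, p_adj`.
#' @export
tfidf_markers <- function(x, clusters = NULL, tfidf_cutoff = 1,
                          p_cutoff = 0.01, return_all = FALSE) {
  stopifnot(is(x, "cell_matrix"))
  if (is.null(clusters)) clusters <- x$meta$cluster
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(x$counts) || anyNA(clusters))
    stop("clusters must label every cell")
  if (length(unique(clusters)) < 2)
    stop("at least two clusters are required")
  bin <- x$counts > 0
  N <- ncol(bin)
  m_global <- Matrix::rowSums(bin)
  global_rate <- m_global / N

  res <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    idx <- which(clusters == cl)
    if (length(idx) == 0) stop("empty cluster: ", cl)
    n_in <- Matrix::rowSums(bin[, idx, drop = FALSE])
    tf <- n_in / length(idx)
    tfidf <- ifelse(tf == 0, 0, tf * log(N / m_global))
    tfidf[global_rate == 1] <- 0
    p <- phyper(n_in - 1, m_global, N - m_global, length(idx),
                lower.tail = FALSE)
    data.frame(gene = rownames(bin), cluster = cl, tf = tf,
               global_rate = global_rate, tfidf = tfidf, p_raw = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- p.adjust(res$p_raw, method = "BH")
  rownames(res) <- NULL
  if (!return_all)
    res <- res[res$tfidf > tfidf_cutoff & res$p_adj < p_cutoff, ,
               drop = FALSE]
  res
}

#' Expressing fraction of each gene within a cell set
#'
#' @param x a [cell_matrix()].
#' @param cells cell ids or column indices (default: all cells).
#' @return Named numeric vector, fraction of the cells with count > 0.
#' @export
expressing_fraction <- function(x, cells = NULL) {
  stopifnot(is(x, "cell_matrix"))
  m <- x$counts
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, colnames(m))
    if (anyNA(cells)) stop("unknown cell id")
    m <- m[, cells, drop = FALSE]
  }
  Matrix::rowSums(m > 0) / ncol(m)
}

#' Stringent cell-type marker sets
#'
#' High-confidence markers per cluster: tf-idf strictly above `tfidf_cutoff`
#' (default 1) with a significant hypergeometric test, then removal of any
#' gene expressed in more than `max_other_fraction` (default 20%) of cells
#' of any other single cluster. An extrinsic negative-control population
#' (e.g. kidney podocytes) should be present as its own cluster so that
#' broadly expressed genes cannot masquerade as lineage markers; if the
#' named control cluster is absent a warning is emitted and the filters run
#' without it.
#'
#' @param x a [cell_matrix()] that includes the control population.
#' @param clusters cluster label per cell (defaults to `meta$cluster`).
#' @param control_cluster name of the extrinsic control cluster.
#' @param tfidf_cutoff,p_cutoff marker thresholds (strict).
#' @param max_other_fraction exclusion threshold on the expressing fraction
#'   in any other single cluster (strict).
#' @return Named list of marker gene sets, one per non-control cluster.
#' @export
stringent_cell_type_markers <- function(x, clusters = NULL,
                                        control_cluster = "podocyte",
                                        tfidf_cutoff = 1, p_cutoff = 0.01,
                                        max_other_fraction = 0.2) {
  stopifnot(is(x, "cell_matrix"))
  if (is.null(clusters)) clusters <- x$meta$cluster
  clusters <- as.character(clusters)
  if (!control_cluster %in% clusters)
    warning("extrinsic control cluster '", control_cluster,
            "' not present; proceeding without it")
  mk <- tfidf_markers(x, clusters, tfidf_cutoff, p_cutoff)
  cl_names <- sort(unique(clusters))
  frac <- vapply(cl_names, function(cl)
    expressing_fraction(x, which(clusters == cl)),
    numeric(nrow(x$counts)))
  sets <- lapply(setdiff(cl_names, control_cluster), function(cl) {
    cand <- mk$gene[mk$cluster == cl]
    if (length(cand) == 0) return(character())
    other <- frac[cand, setdiff(cl_names, cl), drop = FALSE]
    cand[apply(other, 1, max) <= max_other_fraction]
  })
  names(sets) <- setdiff(cl_names, control_cluster)
  sets
}

#' Merge tumor marker lists from two datasets
#'
#' Combines the tumor-vs-rest marker tables of two independently processed
#' tumor datasets: takes the union of genes, averages the tf-idf over the
#' lists in which a gene appears (a gene found in only one list contributes
#' its single value), keeps genes with average tf-idf strictly above the
#' cutoff, and finally drops genes expressed by more than
#' `max_leukocyte_fraction` of leukocytes.
#'
#' @param list_a,list_b marker tables with columns `gene` and `tfidf`
#'   (e.g. from [tfidf_markers()] restricted to the tumor cluster).
#' @param tfidf_cutoff average tf-idf cutoff (strict; default 0.85).
#' @param leukocyte_fraction named per-gene expressing fraction among
#'   leukocytes; genes missing from it are kept.
#' @param max_leukocyte_fraction exclusion threshold (strict; default 0.25).
#' @return Character vector of merged tumor marker genes.
#' @export
merge_tumor_markers <- function(list_a, list_b, tfidf_cutoff = 0.85,
                                leukocyte_fraction = NULL,
                                max_leukocyte_fraction = 0.25) {
  stopifnot(all(c("gene", "tfidf") %in% names(list_a)),
            all(c("gene", "tfidf") %in% names(list_b)))
  genes <- union(list_a$gene, list_b$gene)
  avg <- vapply(genes, function(g) {
    v <- c(list_a$tfidf[list_a$gene == g], list_b$tfidf[list_b$gene == g])
    mean(v)
  }, numeric(1))
  keep <- genes[avg > tfidf_cutoff]
  if (!is.null(leukocyte_fraction)) {
    lf <- leukocyte_fraction[keep]
    keep <- keep[is.na(lf) | lf <= max_leukocyte_fraction]
  }
  keep
}

#' Rank-sum differential expression with a detection prefilter
#'
#' Two-sided Wilcoxon rank-sum tests on log-normalized expression between
#' two disjoint cell groups. Genes detected (count > 0) in fewer than
#' `min_detect` of the cells of both groups are excluded before testing
#' (i.e. a gene is tested when its detection frequency reaches `min_detect`
#' in at least one group). A constant gene gets p = 1.
#'
#' @param x a [cell_matrix()] with logcounts.
#' @param group_a,group_b disjoint cell-id vectors, each with >= 3 cells.
#' @param min_detect detection-frequency prefilter (default 0.25).
#' @param p_cutoff adjusted-p cutoff applied when `return_all = FALSE`.
#' @param return_all return all tested genes rather than significant ones.
#' @return `data.frame` with `gene, log2fc, statistic, p_raw, p_adj,
#'   detect_a, detect_b` (log2fc of mean depth-normalized expression,
#'   positive = higher in `group_a`).
#' @export
ranksum_de <- function(x, group_a, group_b, min_detect = 0.25,
                       p_cutoff = 0.01, return_all = FALSE) {
  lc <- logcounts_or_stop(x)
  ia <- match(group_a, colnames(lc)); ib <- match(group_b, colnames(lc))
  if (anyNA(ia) || anyNA(ib)) stop("unknown cell id in group")
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  if (length(ia) < 3 || length(ib) < 3)
    stop("each group needs at least 3 cells")
  det_a <- expressing_fraction(x, ia)
  det_b <- expressing_fraction(x, ib)
  test_genes <- which(pmax(det_a, det_b) >= min_detect)
  if (length(test_genes) == 0)
    return(data.frame(gene = character(), log2fc = numeric(),
                      statistic = numeric(), p_raw = numeric(),
                      p_adj = numeric(), detect_a = numeric(),
                      detect_b = numeric()))
  la <- as.matrix(lc[test_genes, ia, drop = FALSE])
  lb <- as.matrix(lc[test_genes, ib, drop = FALSE])
  p <- numeric(length(test_genes)); w <- numeric(length(test_genes))
  for (i in seq_along(test_genes)) {
    va <- la[i, ]; vb <- lb[i, ]
    if (var(c(va, vb)) == 0) { p[i] <- 1; w[i] <- NA_real_; next }
    wt <- suppressWarnings(wilcox.test(va, vb, exact = FALSE))
    p[i] <- wt$p.value; w[i] <- unname(wt$statistic)
  }
  mean_a <- rowMeans(expm1(la)); mean_b <- rowMeans(expm1(lb))
  res <- data.frame(gene = rownames(lc)[test_genes],
                    log2fc = log2((mean_a + 1) / (mean_b + 1)),
                    statistic = w, p_raw = p,
                    p_adj = p.adjust(p, method = "BH"),
                    detect_a = det_a[test_genes],
                    detect_b = det_b[test_genes],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (!return_all) res <- res[res$p_adj < p_cutoff, , drop = FALSE]
  res
}

#' Negative binomial DE with genewise dispersion (no shrinkage)
#'
#' Contrast of two cell groups under a per-gene NB model in which the
#' overdispersion is estimated for each gene independently — no information
#' sharing across genes (edgeR with `prior.df = 0`) — followed by a
#' quasi-likelihood F test. Intended for settings with enough cells per
#' group to estimate genewise dispersion robustly; optionally restricts to
#' G1-phase cells (both cell-cycle scores <= 0) so proliferation does not
#' confound the contrast.
#'
#' @param x a [cell_matrix()].
#' @param group_a,group_b disjoint cell-id vectors, each with >= `min_cells`.
#' @param g1_only restrict to G1 cells (requires `s_score`, `g2m_score`).
#' @param min_cells minimum cells per group after any G1 filter (default
#'   10).
#' @return `data.frame` with `gene, log2fc, statistic, p_raw, p_adj,
#'   detect_a, detect_b, status` (`tested` or `all_zero`; all-zero genes are
#'   excluded from testing with p = NA).
#' @export
nb_de_genewise <- function(x, group_a, group_b, g1_only = FALSE,
                           min_cells = 10) {
  stopifnot(is(x, "cell_matrix"))
  if (g1_only) {
    s <- x$meta$s_score; g <- x$meta$g2m_score
    if (anyNA(s) || anyNA(g))
      stop("g1_only requires complete s_score and g2m_score metadata")
    g1 <- x$meta$cell[s <= 0 & g <= 0]
    group_a <- intersect(group_a, g1)
    group_b <- intersect(group_b, g1)
  }
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  if (length(group_a) < min_cells || length(group_b) < min_cells)
    stop("groups of fewer than ", min_cells, " cells cannot support ",
         "genewise dispersion; use nb_glm_fixed_dispersion() instead")
  cells <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))),
                levels = c("b", "a"))
  cm <- as.matrix(x$counts[, match(cells, colnames(x$counts)), drop = FALSE])
  nonzero <- rowSums(cm) > 0
  design <- model.matrix(~grp)
  y <- edgeR::DGEList(counts = cm[nonzero, , drop = FALSE])
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, design, prior.df = 0)
  fit <- edgeR::glmQLFit(y, design)
  tst <- edgeR::glmQLFTest(fit, coef = 2)
  tab <- tst$table
  det_a <- expressing_fraction(x, group_a)
  det_b <- expressing_fraction(x, group_b)
  res <- data.frame(gene = rownames(x$counts),
                    log2fc = NA_real_, statistic = NA_real_,
                    p_raw = NA_real_, p_adj = NA_real_,
                    detect_a = det_a, detect_b = det_b,
                    status = ifelse(nonzero, "tested", "all_zero"),
                    stringsAsFactors = FALSE)
  i <- match(rownames(tab), res$gene)
  res$log2fc[i] <- tab$logFC
  res$statistic[i] <- tab$F
  res$p_raw[i] <- tab$PValue
  res$p_adj[i] <- p.adjust(tab$PValue, method = "BH")
  rownames(res) <- NULL
  res
}

#' Hypergeometric enrichment of a marker set in a hit list
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between a hit list (e.g. differentially expressed genes) and a
#' marker set, drawn from a common gene universe.
#'
#' @param hit_list,marker_set,universe character gene vectors;
#'   `hit_list` and `marker_set` must be subsets of `universe`.
#' @return List with `overlap`, `expected`, and `p`.
#' @export
hypergeometric_enrichment <- function(hit_list, marker_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hit_list <- unique(hit_list); marker_set <- unique(marker_set)
  if (!all(hit_list %in% universe) || !all(marker_set %in% universe))
    stop("hit_list and marker_set must be subsets of the universe")
  k <- length(intersect(hit_list, marker_set))
  m <- length(marker_set); n <- length(universe) - m
  d <- length(hit_list)
  list(overlap = k,
       expected = d * m / length(universe),
       p = phyper(k - 1, m, n, d, lower.tail = FALSE))
}
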