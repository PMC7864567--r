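#' Train per-cell-type elastic-net logistic reference models
#'
#' Fits one-vs-rest binomial logistic regressions with elastic-net
#' regularization (mixing parameter `alpha`, default 0.99) on log-normalized
#' reference expression, one model per cell type. One-vs-rest fits (rather
#' than a single multinomial fit) keep the later choice of omitting softmax
#' well defined per class. The regularization strength is chosen by
#' cross-validated deviance with a seeded, fixed fold assignment, so training
#' is deterministic given the seed.
#'
#' @param reference a [cell_matrix()] with logcounts ([normalize_log()]).
#' @param labels cell-type label per reference cell (character or factor, in
#'   column order, or named by cell).
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param min_cells minimum cells per class.
#' @param nfolds cross-validation folds.
#' @param lambda_rule `"lambda.1se"` (strongest penalty within one standard
#'   error of the minimum deviance; default) or `"lambda.min"`.
#' @param seed RNG seed controlling fold assignment.
#' @return An object of class `reference_model`: class labels, shared gene
#'   list, per-class coefficient vectors and intercepts, `alpha`, per-class
#'   `lambda`.
#' @export
train_reference_model <- function(reference, labels, alpha = 0.99,
                                  min_cells = 20, nfolds = 10,
                                  lambda_rule = c("lambda.1se", "lambda.min"),
                                  seed = 1) {
  stopifnot(is(reference, "cell_matrix"))
  lambda_rule <- match.arg(lambda_rule)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  lc <- logcounts_or_stop(reference)
  if (!is.null(names(labels)))
    labels <- labels[colnames(lc)]
  labels <- as.character(labels)
  if (length(labels) != ncol(lc) || anyNA(labels))
    stop("labels must cover every reference cell")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("at least two classes are required")
  small <- names(sizes)[sizes < min_cells]
  if (length(small) > 0)
    stop("classes below the minimum of ", min_cells, " cells: ",
         paste(small, collapse = ", "))

  x <- Matrix::t(lc)
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(x)))
  classes <- sort(unique(labels))
  fits <- lapply(classes, function(cls) {
    y <- as.integer(labels == cls)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                            foldid = foldid, standardize = TRUE)
    lam <- cv[[lambda_rule]]
    beta <- as.numeric(coef(cv, s = lam))
    list(intercept = beta[1],
         coefficients = setNames(beta[-1], rownames(lc)),
         lambda = lam)
  })
  names(fits) <- classes
  structure(list(
    class_labels = classes,
    gene_list = rownames(lc),
    coefficients = vapply(fits, `[[`, numeric(nrow(lc)), "coefficients"),
    intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
    alpha = alpha,
    lambda = vapply(fits, `[[`, numeric(1), "lambda")),
    class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model: %d classes over %d genes (alpha = %g)\n",
              length(x$class_labels), length(x$gene_list), x$alpha))
  nz <- colSums(x$coefficients != 0)
  cat("  nonzero coefficients per class:\n")
  print(nz)
  invisible(x)
}

#' Score query cells against a reference model
#'
#' Evaluates each class's linear predictor on the query's log-normalized
#' expression and reports the raw logit. No softmax normalization is applied
#' across classes, so a query cell that resembles none of the reference
#' types can legitimately score negative for every class. Genes in the model
#' but absent from the query are imputed as zero. When cluster labels are
#' present, per-cluster arithmetic means of the member-cell logits are also
#' returned.
#'
#' @param model a [train_reference_model()] fit.
#' @param query a [cell_matrix()] with logcounts.
#' @param cluster_col metadata column used for cluster averaging (set `NULL`
#'   to skip).
#' @return An object of class `similarity_scores`: `cell_logits` (cell x
#'   class matrix) and `cluster_logits` (cluster x class matrix or `NULL`).
#' @export
score_cells <- function(model, query, cluster_col = "cluster") {
  stopifnot(is(model, "reference_model"), is(query, "cell_matrix"))
  lc <- logcounts_or_stop(query)
  shared <- intersect(model$gene_list, rownames(lc))
  if (length(shared) == 0)
    stop("query shares no genes with the model gene list")
  x <- Matrix::t(lc[shared, , drop = FALSE])
  beta <- model$coefficients[shared, , drop = FALSE]
  logits <- as.matrix(x %*% beta) +
    rep(model$intercepts, each = nrow(x))
  dimnames(logits) <- list(colnames(lc), model$class_labels)

  cluster_logits <- NULL
  if (!is.null(cluster_col) && cluster_col %in% names(query$meta) &&
      !all(is.na(query$meta[[cluster_col]]))) {
    cl <- as.character(query$meta[[cluster_col]])
    cluster_logits <- do.call(rbind, lapply(split(seq_along(cl), cl),
      function(i) colMeans(logits[i, , drop = FALSE])))
  }
  structure(list(cell_logits = logits, cluster_logits = cluster_logits),
            class = "similarity_scores")
}

#' Split a score vector into low/high groups by k-means
#'
#' Partitions a one-dimensional score (e.g. the sympathoblast similarity
#' logit of high-risk tumor cells) into `k = 2` groups with a seeded
#' multi-start k-means; the group with the smaller mean is labelled
#' `"low"`, the other `"high"`.
#'
#' @param scores numeric vector (optionally named by cell).
#' @param k number of clusters (default 2).
#' @param seed RNG seed for the multi-start.
#' @return Factor of labels `"low"`/`"high"` (or `"group1"..` for k > 2,
#'   ordered by mean), named like `scores`.
#' @export
kmeans_split_scores <- function(scores, k = 2, seed = 1) {
  v <- as.numeric(scores)
  if (anyNA(v)) stop("scores must be numeric and complete")
  if (length(unique(v)) < k)
    stop("degenerate split: need at least ", k, " distinct score values")
  set.seed(seed)
  km <- kmeans(matrix(v, ncol = 1), centers = k, nstart = 25, iter.max = 100)
  ord <- order(km$centers[, 1])
  lab <- if (k == 2) c("low", "high") else paste0("group", seq_len(k))
  out <- factor(lab[match(km$cluster, ord)], levels = lab)
  names(out) <- names(scores)
  out
}
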