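#' Presence threshold from the pooled log2(TPM) distribution
#'
#' The expression level above which a gene counts as "present" in a bulk
#' sample: the mode (argmax of a Gaussian kernel density estimate,
#' Silverman's bandwidth) of log2(TPM) pooled over all strictly positive
#' entries across all genes and samples. Zeros are excluded — log2 of zero
#' is undefined and zeros would otherwise dominate the density.
#'
#' @param cohort a `bulk_cohort` (or a bare sample-by-gene TPM matrix).
#' @param min_positive minimum number of strictly positive entries required.
#' @return The threshold on the log2(TPM) scale (a single numeric).
#' @export
presence_threshold <- function(cohort, min_positive = 100) {
  tpm <- if (is(cohort, "bulk_cohort")) cohort$tpm else cohort
  v <- log2(tpm[tpm > 0])
  if (length(v) == 0) stop("all-zero TPM matrix: no positive entries")
  if (length(v) < min_positive)
    stop("need at least ", min_positive, " positive TPM entries")
  if (var(v) == 0) return(v[1])  # point mass: the peak is the unique value
  d <- density(v, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Per-gene marker presence fractions in a bulk cohort
#'
#' A gene is "present" in a sample when its log2(TPM) strictly exceeds the
#' presence threshold. For each marker set this computes the per-gene
#' fraction of samples (optionally within strata, e.g. risk groups) where
#' the gene is present, and summarizes each set by the median and
#' interquartile range over its genes. Marker genes absent from the cohort
#' are recorded and excluded from summaries.
#'
#' @param cohort a `bulk_cohort`.
#' @param marker_sets named list of cell-type marker gene sets.
#' @param strata optional per-sample stratification labels (named by sample
#'   or aligned with rows of the TPM matrix).
#' @param threshold presence threshold; computed via [presence_threshold()]
#'   when `NULL`.
#' @return List with `per_gene` (`data.frame`: set, gene, stratum,
#'   fraction_present), `summary` (median and IQR per set and stratum),
#'   `missing` (genes per set absent from the cohort), and `threshold`.
#' @export
marker_presence_fraction <- function(cohort, marker_sets, strata = NULL,
                                     threshold = NULL) {
  stopifnot(is(cohort, "bulk_cohort"), is.list(marker_sets))
  if (is.null(threshold)) threshold <- presence_threshold(cohort)
  tpm <- cohort$tpm
  if (is.null(strata)) {
    strata <- rep("all", nrow(tpm))
  } else if (!is.null(names(strata))) {
    strata <- strata[rownames(tpm)]
  }
  strata <- as.character(strata)
  present <- log2(pmax(tpm, .Machine$double.xmin)) > threshold & tpm > 0

  if (length(marker_sets) == 0 ||
      !any(unlist(marker_sets) %in% colnames(tpm)))
    stop("none of the marker genes are present in the cohort")
  per_gene <- do.call(rbind, lapply(names(marker_sets), function(set) {
    genes <- intersect(marker_sets[[set]], colnames(tpm))
    if (length(genes) == 0) return(NULL)
    do.call(rbind, lapply(sort(unique(strata)), function(st) {
      rows <- strata == st
      data.frame(set = set, gene = genes, stratum = st,
                 fraction_present =
                   colMeans(present[rows, genes, drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_gene) <- NULL
  missing <- lapply(marker_sets, function(g) setdiff(g, colnames(tpm)))
  summary <- do.call(rbind, lapply(split(per_gene,
                                         per_gene[c("set", "stratum")],
                                         drop = TRUE), function(d) {
    q <- quantile(d$fraction_present, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(set = d$set[1], stratum = d$stratum[1], n_genes = nrow(d),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_gene = per_gene, summary = summary, missing = missing,
       threshold = threshold)
}

#' Risk stratification from age, MYCN status, and stage
#'
#' Classifies bulk samples into risk groups using only covariates, for
#' cohorts that lack curated risk labels: low risk when age at diagnosis is
#' under 18 months and MYCN amplification is negative; high risk when age is
#' over 18 months and MYCN amplification is positive. Stage 4S samples are
#' always unclassified, as is any other covariate combination or a sample
#' with missing or unknown age/MYCN.
#'
#' @param cohort a `bulk_cohort` with covariates `age_months`,
#'   `mycn_status`, `stage`.
#' @return `data.frame` with `sample`, `risk`
#'   (`low`/`high`/`unclassified`), and `reason` for unclassified samples.
#' @export
stratify_risk_seqc <- function(cohort) {
  stopifnot(is(cohort, "bulk_cohort"))
  cov <- cohort$covariates
  needed <- c("age_months", "mycn_status", "stage")
  if (!all(needed %in% names(cov)))
    stop("covariates must include: ", paste(needed, collapse = ", "))
  n <- nrow(cov)
  risk <- rep("unclassified", n)
  reason <- rep("", n)
  missing <- is.na(cov$age_months) | is.na(cov$mycn_status) |
    cov$mycn_status == "unknown"
  reason[missing] <- "missing age or MYCN status"
  is4s <- !is.na(cov$stage) & cov$stage == "4S"
  reason[is4s] <- "stage 4S excluded"
  ok <- !missing & !is4s
  low <- ok & cov$age_months < 18 & cov$mycn_status == "neg"
  high <- ok & cov$age_months > 18 & cov$mycn_status == "pos"
  risk[low] <- "low"; risk[high] <- "high"
  reason[ok & !low & !high] <- "covariate combination matches neither rule"
  data.frame(sample = cov$sample, risk = risk, reason = reason,
             stringsAsFactors = FALSE)
}

#' Select tumors arising outside the adrenal gland
#'
#' Retains samples whose free-text site description is non-empty and
#' contains none of the stop-words "kidney", "adrenal", "abdominal",
#' "abdomen", "unknown", "retroperitoneum", "other" (case-insensitive
#' substring match). Samples with an absent description are excluded.
#'
#' @param cohort a `bulk_cohort` with a `site_description` covariate.
#' @return Character vector of retained sample ids.
#' @export
filter_extra_adrenal <- function(cohort) {
  stopifnot(is(cohort, "bulk_cohort"))
  cov <- cohort$covariates
  if (!"site_description" %in% names(cov))
    stop("covariates must include site_description")
  desc <- cov$site_description
  stop_words <- c("kidney", "adrenal", "abdominal", "abdomen", "unknown",
                  "retroperitoneum", "other")
  has_word <- Reduce(`|`, lapply(stop_words, function(w)
    grepl(w, desc, ignore.case = TRUE, fixed = FALSE)))
  keep <- !is.na(desc) & trimws(desc) != "" & !has_word
  cov$sample[keep]
}

#' Covariate-adjusted NB differential expression with fixed dispersion
#'
#' Per-gene negative binomial regression of bulk raw counts on age, MYCN
#' status, and risk group, with the dispersion fixed at
#' `sqrt_dispersion^2` (default 0.4^2 = 0.16) because bulk cohorts carry no
#' genuine biological replicates from which to estimate it. The risk-group
#' coefficient is tested with a quasi-likelihood F test (edgeR), and genes
#' are flagged significant under the reporting rule |log2FC| > 1 and
#' FDR < 0.05. Refuses to run on TPM-only cohorts: the NB model needs raw
#' counts.
#'
#' @param cohort a `bulk_cohort` with a `counts` matrix (sample-by-gene)
#'   and covariates `age_months`, `mycn_status`, plus the risk labels.
#' @param risk per-sample risk labels (named by sample, or aligned);
#'   defaults to the `risk` covariate. Samples with labels outside
#'   `risk_levels` are dropped.
#' @param sqrt_dispersion square root of the fixed NB overdispersion.
#' @param risk_levels the two levels contrasted; the second is the
#'   numerator of the fold change.
#' @return `data.frame` with `gene, log2fc, statistic, p_raw, p_adj,
#'   significant` (positive log2fc = higher in `risk_levels[2]`).
#' @export
nb_glm_fixed_dispersion <- function(cohort, risk = NULL,
                                    sqrt_dispersion = 0.4,
                                    risk_levels = c("low", "high")) {
  stopifnot(is(cohort, "bulk_cohort"))
  if (is.null(cohort$counts))
    stop("raw counts are required; TPM alone cannot support the NB model")
  cov <- cohort$covariates
  if (is.null(risk)) risk <- cov$risk
  if (!is.null(names(risk))) risk <- risk[cov$sample]
  keep <- risk %in% risk_levels
  if (sum(keep) < 4) stop("too few samples in the contrasted risk groups")
  counts <- t(cohort$counts[keep, , drop = FALSE])  # genes x samples
  cov <- cov[keep, , drop = FALSE]
  risk <- factor(risk[keep], levels = risk_levels)
  mycn <- factor(cov$mycn_status)
  design <- if (nlevels(mycn) > 1)
    model.matrix(~cov$age_months + mycn + risk)
  else model.matrix(~cov$age_months + risk)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("design matrix is rank deficient; aliased columns: ",
         paste(colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]],
               collapse = ", "))
  nonzero <- rowSums(counts) > 0
  y <- edgeR::DGEList(counts = counts[nonzero, , drop = FALSE])
  y <- edgeR::calcNormFactors(y)
  fit <- edgeR::glmQLFit(y, design, dispersion = sqrt_dispersion^2)
  tst <- edgeR::glmQLFTest(fit, coef = ncol(design))
  tab <- tst$table
  res <- data.frame(gene = rownames(counts), log2fc = NA_real_,
                    statistic = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  i <- match(rownames(tab), res$gene)
  res$log2fc[i] <- tab$logFC
  res$statistic[i] <- tab$F
  res$p_raw[i] <- tab$PValue
  res$p_adj[i] <- p.adjust(tab$PValue, method = "BH")
  res$significant <- !is.na(res$p_adj) & res$p_adj < 0.05 &
    abs(res$log2fc) > 1
  rownames(res) <- NULL
  res
}

#' Rank fetal cancer transcripts by expression outside the brain
#'
#' Identifies transcripts shared by cancer cells and the fetal medulla and
#' ranks them by how little they are expressed in postnatal non-brain
#' tissues (candidates with restricted postnatal expression rank first).
#' Filters, per tumor dataset: expressed in at least 50% of cancer cells
#' and in no more than 20% of cells of any other single cluster; then the
#' intersection across datasets; then expressed in at least 10% of adrenal
#' medullary reference cells. Remaining genes are sorted by increasing mean
#' log2(TPM + 1) over the non-brain samples of a normal-tissue panel.
#'
#' @param cancer_stats list of per-dataset `data.frame`s with columns
#'   `gene`, `cancer_detect_fraction`, `max_other_cluster_fraction`.
#' @param medulla_detect named per-gene expressing fraction among adrenal
#'   medullary reference cells (see [expressing_fraction()]).
#' @param normal_panel a `bulk_cohort` whose covariates carry a `tissue`
#'   label.
#' @param brain_pattern regular expression identifying brain tissues.
#' @param min_cancer_detect,max_other_cluster,min_medulla_detect filter
#'   thresholds.
#' @param top_k rows to flag in the `top` attribute (default 25).
#' @return `data.frame` of candidate genes sorted by ascending non-brain
#'   expression, with columns `gene, medulla_detect, nonbrain_mean_log2tpm`.
#' @export
fetal_cancer_transcripts <- function(cancer_stats, medulla_detect,
                                     normal_panel,
                                     brain_pattern = "brain",
                                     min_cancer_detect = 0.5,
                                     max_other_cluster = 0.2,
                                     min_medulla_detect = 0.1,
                                     top_k = 25) {
  stopifnot(is.list(cancer_stats), length(cancer_stats) >= 1,
            is(normal_panel, "bulk_cohort"))
  per_set <- lapply(cancer_stats, function(d) {
    d$gene[d$cancer_detect_fraction >= min_cancer_detect &
             d$max_other_cluster_fraction <= max_other_cluster]
  })
  shared <- Reduce(intersect, per_set)
  shared <- shared[!is.na(medulla_detect[shared]) &
                     medulla_detect[shared] >= min_medulla_detect]
  if (length(shared) == 0) {
    message("no fetal cancer transcripts pass the filters")
    return(data.frame(gene = character(), medulla_detect = numeric(),
                      nonbrain_mean_log2tpm = numeric()))
  }
  tissue <- normal_panel$covariates$tissue
  if (is.null(tissue)) stop("normal_panel covariates need a tissue label")
  nonbrain <- !grepl(brain_pattern, tissue, ignore.case = TRUE)
  if (!any(nonbrain)) stop("normal panel has no non-brain tissues")
  shared <- intersect(shared, colnames(normal_panel$tpm))
  expr <- colMeans(log2(normal_panel$tpm[nonbrain, shared, drop = FALSE] + 1))
  res <- data.frame(gene = shared, medulla_detect = medulla_detect[shared],
                    nonbrain_mean_log2tpm = expr, stringsAsFactors = FALSE)
  res <- res[order(res$nonbrain_mean_log2tpm, res$gene), ]
  rownames(res) <- NULL
  attr(res, "top") <- head(res$gene, top_k)
  res
}
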