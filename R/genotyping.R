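#' Copy-number segment table
#'
#' Genomic intervals (0-based, half-open) carrying allele-specific copy
#' numbers. The expected major-haplotype fraction of mRNA reads is
#' `major_cn / (major_cn + minor_cn)`, and 1 when the minor allele is lost
#' entirely; only segments with allelic imbalance (fraction in \[0.5, 1\])
#' are meaningful for genotyping.
#'
#' @param chrom,start,end interval coordinates (start < end, 0-based
#'   half-open).
#' @param major_cn,minor_cn non-negative integer copy numbers of the two
#'   parental haplotypes (major >= minor).
#' @return A `data.frame` of class `copy_number_segments` with an
#'   `expected_major_fraction` column.
#' @export
copy_number_segments <- function(chrom, start, end, major_cn, minor_cn) {
  seg <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), major_cn = as.integer(major_cn),
                    minor_cn = as.integer(minor_cn),
                    stringsAsFactors = FALSE)
  seg$expected_major_fraction <- ifelse(
    seg$minor_cn == 0, 1, seg$major_cn / (seg$major_cn + seg$minor_cn))
  class(seg) <- c("copy_number_segments", "data.frame")
  validate_segments(seg)
}

validate_segments <- function(seg) {
  needed <- c("chrom", "start", "end", "expected_major_fraction")
  if (!all(needed %in% names(seg)))
    stop("segments must carry columns: ", paste(needed, collapse = ", "))
  if (any(seg$start >= seg$end)) stop("segment start must be < end")
  if (any(seg$expected_major_fraction < 0.5 |
          seg$expected_major_fraction > 1))
    stop("expected_major_fraction must lie in [0.5, 1]")
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("segments overlap on ", ch)
  }
  invisible(seg)
}

snp_id <- function(chrom, pos) paste0(chrom, ":", pos)

#' Phase heterozygous SNPs across a copy-number segment
#'
#' Assigns each SNP's alleles to the major/minor haplotype by pooling allele
#' counts across all cells: within a copy-number-imbalanced segment the
#' major haplotype is over-represented in aggregate, so the allele with the
#' larger pooled count is taken as major. Ties are broken deterministically
#' toward the reference allele and flagged low confidence.
#'
#' @param counts allele count table: `data.frame` with columns
#'   `cell, chrom, pos, ref_count, alt_count`.
#' @param segments a [copy_number_segments()] table.
#' @param het_snps `data.frame` of heterozygous SNPs with columns
#'   `chrom, pos` (optionally `ref_allele`, `alt_allele`).
#' @param min_pooled_depth SNPs with pooled depth below this are dropped.
#' @return `data.frame` of class `phased_snps`: one row per phased SNP with
#'   `major_is_alt`, `phase_confidence` (pooled major fraction), `tied`
#'   flag, and the owning `segment` index. SNPs outside every segment are
#'   skipped with a warning.
#' @export
phase_snps <- function(counts, segments, het_snps, min_pooled_depth = 1) {
  segments <- validate_segments(segments)
  stopifnot(all(c("chrom", "pos") %in% names(het_snps)),
            all(c("cell", "chrom", "pos", "ref_count", "alt_count") %in%
                  names(counts)))
  seg_of <- function(chrom, pos) {
    hit <- which(segments$chrom == chrom & segments$start <= pos &
                   pos < segments$end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  het_snps$segment <- mapply(seg_of, het_snps$chrom, het_snps$pos)
  outside <- is.na(het_snps$segment)
  if (any(outside)) {
    warning(sum(outside), " SNP(s) outside all imbalanced segments skipped")
    het_snps <- het_snps[!outside, , drop = FALSE]
  }
  id <- snp_id(het_snps$chrom, het_snps$pos)
  cid <- snp_id(counts$chrom, counts$pos)
  ref_pool <- vapply(id, function(i) sum(counts$ref_count[cid == i]),
                     numeric(1))
  alt_pool <- vapply(id, function(i) sum(counts$alt_count[cid == i]),
                     numeric(1))
  depth <- ref_pool + alt_pool
  keep <- depth >= max(min_pooled_depth, 1)
  het_snps <- het_snps[keep, , drop = FALSE]
  ref_pool <- ref_pool[keep]; alt_pool <- alt_pool[keep]
  depth <- depth[keep]
  out <- data.frame(
    chrom = het_snps$chrom, pos = het_snps$pos,
    ref_allele = if ("ref_allele" %in% names(het_snps))
      het_snps$ref_allele else NA_character_,
    alt_allele = if ("alt_allele" %in% names(het_snps))
      het_snps$alt_allele else NA_character_,
    major_is_alt = alt_pool > ref_pool,
    segment = het_snps$segment,
    phase_confidence = pmax(ref_pool, alt_pool) / depth,
    tied = alt_pool == ref_pool,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phased_snps", "data.frame")
  out
}

#' Posterior probability of the tumor genotype per cell
#'
#' For each cell, aggregates major/minor-haplotype read counts over the
#' phased SNPs of each copy-number segment and contrasts two genotype
#' hypotheses: under the tumor genome the major-haplotype read fraction in
#' segment s is the segment's expected major fraction (clipped into
#' `[error_rate, 1 - error_rate]`); under a diploid genome it is 0.5. The
#' likelihoods are per-segment binomial products and the posterior follows
#' from Bayes' rule with prior `prior_tumor`. A cell with no informative
#' reads keeps the prior (logit 0 at a flat prior: "no information").
#'
#' @param counts allele count table (`cell, chrom, pos, ref_count,
#'   alt_count`).
#' @param phased a [phase_snps()] table.
#' @param segments a [copy_number_segments()] table.
#' @param error_rate read-level error; expected fractions are clipped away
#'   from 0 and 1 by this amount. Must lie in (0, 0.5).
#' @param prior_tumor prior probability of the tumor genotype, in (0, 1).
#' @param cells optional character vector of cells to report (cells absent
#'   from `counts` get the prior and an `uninformative` call).
#' @return `data.frame` of class `genotype_posterior`: per cell `k_major`,
#'   `n_total`, `posterior_tumor`, `logit`, and `call` in
#'   `definitive_tumor` (> 0.99), `definitive_normal` (< 0.01), or
#'   `uninformative`.
#' @export
compute_posterior <- function(counts, phased, segments, error_rate = 0.01,
                              prior_tumor = 0.5, cells = NULL) {
  segments <- validate_segments(segments)
  stopifnot(is(phased, "data.frame"))
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  if (prior_tumor <= 0 || prior_tumor >= 1)
    stop("prior_tumor must lie in (0, 1)")

  pid <- snp_id(phased$chrom, phased$pos)
  cid <- snp_id(counts$chrom, counts$pos)
  m <- match(cid, pid)
  use <- !is.na(m)
  cc <- counts[use, , drop = FALSE]
  seg <- phased$segment[m[use]]
  major_is_alt <- phased$major_is_alt[m[use]]
  k_major <- ifelse(major_is_alt, cc$alt_count, cc$ref_count)
  n <- cc$ref_count + cc$alt_count

  f_seg <- pmin(pmax(segments$expected_major_fraction, error_rate),
                1 - error_rate)
  if (nrow(cc) > 0) {
    key <- paste(cc$cell, seg, sep = "\r")  # \r cannot occur in a cell id
    k_by <- tapply(k_major, key, sum)
    n_by <- tapply(n, key, sum)
    parts <- strsplit(names(k_by), "\r", fixed = TRUE)
    cell_by <- vapply(parts, `[[`, character(1), 1)
    seg_by <- as.integer(vapply(parts, `[[`, character(1), 2))
  } else {
    k_by <- n_by <- numeric(0)
    cell_by <- character(0)
    seg_by <- integer(0)
  }

  ll_t <- dbinom(k_by, n_by, f_seg[seg_by], log = TRUE)
  ll_n <- dbinom(k_by, n_by, 0.5, log = TRUE)

  all_cells <- if (is.null(cells)) sort(unique(counts$cell)) else cells
  agg <- function(v, cells_of) {
    res <- setNames(numeric(length(all_cells)), all_cells)
    if (length(v) == 0) return(res)
    out <- tapply(v, cells_of, sum)
    res[names(out)[names(out) %in% all_cells]] <-
      out[names(out) %in% all_cells]
    res
  }
  llt <- agg(ll_t, cell_by)
  lln <- agg(ll_n, cell_by)
  kk <- agg(as.numeric(k_by), cell_by)
  nn <- agg(as.numeric(n_by), cell_by)

  # posterior on the log scale for numerical stability at high depth
  log_odds <- log(prior_tumor) - log(1 - prior_tumor) + llt - lln
  posterior <- 1 / (1 + exp(-log_odds))
  call <- ifelse(posterior > 0.99, "definitive_tumor",
                 ifelse(posterior < 0.01, "definitive_normal",
                        "uninformative"))
  out <- data.frame(cell = all_cells, k_major = kk, n_total = nn,
                    posterior_tumor = posterior, logit = log_odds,
                    call = call, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("genotype_posterior", "data.frame")
  out
}

#' Cluster-level tumor/normal verdicts
#'
#' A cluster is called tumor when it contains strictly more definitively
#' tumor cells (posterior > 0.99) than definitively normal cells
#' (posterior < 0.01). The cluster-average posterior is reported alongside.
#'
#' @param posteriors a [compute_posterior()] table.
#' @param clusters named cluster label per cell (names = cell ids), or a
#'   vector aligned with `posteriors$cell`.
#' @return `data.frame` with per-cluster counts of each call, the mean
#'   posterior, and the verdict (`tumor` / `not_tumor`).
#' @export
classify_clusters <- function(posteriors, clusters) {
  stopifnot(is(posteriors, "genotype_posterior"))
  if (!is.null(names(clusters))) {
    if (!all(posteriors$cell %in% names(clusters)))
      stop("every cell needs a cluster label")
    clusters <- clusters[posteriors$cell]
  }
  cl <- as.character(clusters)
  stopifnot(length(cl) == nrow(posteriors))
  res <- do.call(rbind, lapply(split(seq_len(nrow(posteriors)), cl),
    function(i) {
      p <- posteriors[i, ]
      n_t <- sum(p$call == "definitive_tumor")
      n_n <- sum(p$call == "definitive_normal")
      data.frame(n_cells = length(i), n_definitive_tumor = n_t,
                 n_definitive_normal = n_n,
                 mean_posterior = mean(p$posterior_tumor),
                 verdict = if (n_t > n_n) "tumor" else "not_tumor",
                 stringsAsFactors = FALSE)
    }))
  res <- cbind(cluster = rownames(res), res)
  rownames(res) <- NULL
  res
}
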