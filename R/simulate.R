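#' Simulate a cell-type-structured single-cell count matrix
#'
#' Draws negative binomial counts for a small panel of fetal-adrenal-like
#' cell types (sympathoblast, chromaffin, SCP, bridge, ...). Each type owns a
#' disjoint block of marker genes expressed `marker_log2fc` log2-fold higher
#' in the owner than in every other type (the block sits at the shared
#' lognormal baseline in its owner and is suppressed elsewhere, the pattern
#' of a genuine lineage marker); per-cell depth is Poisson around
#' `mean_umis` and gene counts are NB with variance `mu + phi mu^2`,
#' `phi = nb_dispersion^2`.
#' Tumor cells (when `tumor_fraction > 0` or `include_tumor`) express the
#' sympathoblast program plus a tumor-specific marker block — the cell state
#' the tumor adopts. An optional extrinsic control type ("podocyte") carries
#' its own marker block and is never part of the adrenal lineage.
#'
#' Per-cell metadata (mitochondrial fraction, doublet score, S and G2M
#' cell-cycle scores) are drawn from declared distributions that keep normal
#' cells clear of the QC thresholds; `qc_violation_rate` plants violations
#' (high mito, high doublet score, low depth, positive cycle score) in a
#' recorded subset of cells.
#'
#' @param config a [sim_config()].
#' @param include_control add an extrinsic control population ("podocyte",
#'   `cells_per_type` cells) outside the adrenal lineage.
#' @param include_tumor add tumor cells; defaults to `tumor_fraction > 0`.
#' @return A list with elements `matrix` (a [cell_matrix()]) and `truth`
#'   (class `ground_truth`: `cell_type_of`, `tumor_status_of`,
#'   `marker_genes`, `expected_profiles`, `qc_violation_of`).
#' @export
simulate_reference_counts <- function(config,
                                      include_control = FALSE,
                                      include_tumor = config$tumor_fraction > 0) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  types <- cell_type_vocabulary()[seq_len(config$n_cell_types)]
  profile_types <- c(types,
                     if (include_tumor) "tumor",
                     if (include_control) "podocyte")

  # disjoint marker blocks; tumor and control own reserved blocks
  block_owner <- c(types, "tumor", "podocyte")
  marker_genes <- lapply(seq_along(block_owner), function(i) {
    genes[seq((i - 1) * config$markers_per_type + 1,
              i * config$markers_per_type)]
  })
  names(marker_genes) <- block_owner

  base <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  names(base) <- genes
  # marker blocks draw from a higher, tighter baseline: lineage markers are
  # reliably detected in the type that expresses them
  block_genes <- unlist(marker_genes, use.names = FALSE)
  base[block_genes] <- rlnorm(length(block_genes), meanlog = 1, sdlog = 0.25)
  # a marker block sits at baseline in its owner and marker_log2fc below it
  # everywhere else, the expression pattern of a genuine lineage marker
  profiles <- vapply(profile_types, function(t) {
    p <- base
    own <- if (t == "tumor") c(marker_genes[["sympathoblast"]],
                               marker_genes[["tumor"]]) else marker_genes[[t]]
    foreign <- setdiff(unlist(marker_genes), own)
    p[foreign] <- p[foreign] * 2^(-config$marker_log2fc)
    p / sum(p)
  }, numeric(config$n_genes))
  rownames(profiles) <- genes

  n_normal <- config$n_cell_types * config$cells_per_type
  n_tumor <- if (include_tumor) {
    tf <- config$tumor_fraction
    if (tf <= 0) tf <- 0.5
    max(1L, round(tf * n_normal / max(1 - tf, 1e-9)))
  } else 0L
  n_control <- if (include_control) config$cells_per_type else 0L
  type_of <- c(rep(types, each = config$cells_per_type),
               rep("tumor", n_tumor), rep("podocyte", n_control))
  n_cells <- length(type_of)
  cells <- sprintf("cell%05d", seq_len(n_cells))
  names(type_of) <- cells

  depth <- rpois(n_cells, config$mean_umis)
  depth[depth == 0] <- 1

  # planted QC violations, assigned cyclically over the four kinds
  violation <- rep("none", n_cells)
  n_viol <- round(config$qc_violation_rate * n_cells)
  if (n_viol > 0) {
    idx <- sample.int(n_cells, n_viol)
    violation[idx] <- rep(c("mito", "doublet", "low_depth", "cycling"),
                          length.out = n_viol)
  }
  depth[violation == "low_depth"] <- pmax(
    1L, rpois(sum(violation == "low_depth"), 150))

  phi <- config$nb_dispersion^2
  mu <- profiles[, type_of, drop = FALSE] *
    rep(depth, each = config$n_genes)
  counts <- if (phi > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / phi)
  } else {
    rpois(length(mu), mu)
  }
  counts <- Matrix::Matrix(matrix(counts, nrow = config$n_genes,
                                  dimnames = list(genes, cells)),
                           sparse = TRUE)

  meta <- data.frame(
    cell = cells,
    mito_fraction = rbeta(n_cells, 2, 38),
    doublet_score = rbeta(n_cells, 1.5, 28.5),
    s_score = rnorm(n_cells, -0.5, 0.2),
    g2m_score = rnorm(n_cells, -0.5, 0.2),
    sample = paste0("sample", 1 + seq_len(n_cells) %% 2),
    cluster = type_of,
    stringsAsFactors = FALSE)
  meta$mito_fraction[violation == "mito"] <-
    runif(sum(violation == "mito"), 0.35, 0.7)
  meta$doublet_score[violation == "doublet"] <-
    runif(sum(violation == "doublet"), 0.25, 0.6)
  meta$s_score[violation == "cycling"] <-
    runif(sum(violation == "cycling"), 0.2, 1)

  truth <- structure(list(
    cell_type_of = type_of,
    tumor_status_of = setNames(ifelse(type_of == "tumor", "tumor", "normal"),
                               cells),
    marker_genes = marker_genes[profile_types],
    expected_profiles = profiles,
    qc_violation_of = setNames(violation, cells)),
    class = "ground_truth")

  list(matrix = cell_matrix(counts, meta), truth = truth)
}

#' Simulate per-cell SNP allele counts under copy-number states
#'
#' For each cell and each copy-number segment, draws a Poisson number of
#' allele-informative reads, splits them uniformly across the segment's
#' heterozygous SNPs, and draws major-haplotype counts binomially. Tumor
#' cells use the segment's expected major-haplotype fraction perturbed by the
#' read-level error (`p = f + e (1 - 2 f)`); normal cells use 0.5. Which
#' observed allele (ref or alt) carries the major haplotype is randomized per
#' SNP and recorded.
#'
#' @param config a [sim_config()]; uses `snps_per_segment`,
#'   `mean_allele_depth`, `allele_error`, `seed`.
#' @param segments a [copy_number_segments()] table (non-overlapping).
#' @param truth a `ground_truth` from [simulate_reference_counts()]; its
#'   `tumor_status_of` must cover all cells to simulate.
#' @return A `data.frame` with columns `cell, chrom, pos, ref_count,
#'   alt_count` (zero-depth rows dropped), with attributes `snps` (the
#'   simulated heterozygous SNPs with their true `major_is_alt` assignment)
#'   and `p_major` (per-status binomial parameters used).
#' @export
simulate_allele_counts <- function(config, segments, truth) {
  validate_sim_config(config)
  segments <- validate_segments(segments)
  stopifnot(is(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  cells <- names(truth$tumor_status_of)

  snps <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    pos <- sort(sample(seq.int(seg$start, seg$end - 1L),
                       config$snps_per_segment))
    data.frame(chrom = seg$chrom, pos = pos,
               ref_allele = sample(c("A", "C", "G", "T"),
                                   config$snps_per_segment, replace = TRUE),
               alt_allele = sample(c("A", "C", "G", "T"),
                                   config$snps_per_segment, replace = TRUE),
               major_is_alt = rbinom(config$snps_per_segment, 1, 0.5) == 1,
               segment = i, stringsAsFactors = FALSE)
  }))

  e <- config$allele_error
  rows <- vector("list", length(cells) * nrow(segments))
  k <- 0L
  for (ci in seq_along(cells)) {
    is_tumor <- truth$tumor_status_of[[cells[ci]]] == "tumor"
    for (si in seq_len(nrow(segments))) {
      f <- segments$expected_major_fraction[si]
      p <- if (is_tumor) f + e * (1 - 2 * f) else 0.5
      n_reads <- rpois(1, config$mean_allele_depth)
      if (n_reads == 0) next
      seg_snps <- snps[snps$segment == si, , drop = FALSE]
      per_snp <- as.integer(rmultinom(1, n_reads,
                                      rep(1, nrow(seg_snps))))
      keep <- per_snp > 0
      if (!any(keep)) next
      k_major <- rbinom(sum(keep), per_snp[keep], p)
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell = cells[ci],
        chrom = seg_snps$chrom[keep],
        pos = seg_snps$pos[keep],
        ref_count = ifelse(seg_snps$major_is_alt[keep],
                           per_snp[keep] - k_major, k_major),
        alt_count = ifelse(seg_snps$major_is_alt[keep],
                           k_major, per_snp[keep] - k_major),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (k > 0) do.call(rbind, rows[seq_len(k)]) else
    data.frame(cell = character(), chrom = character(), pos = integer(),
               ref_count = integer(), alt_count = integer())
  rownames(out) <- NULL
  attr(out, "snps") <- snps
  attr(out, "p_major") <- c(
    tumor = segments$expected_major_fraction +
      e * (1 - 2 * segments$expected_major_fraction),
    normal = 0.5)
  out
}

#' Simulate a bulk TPM cohort with clinical covariates
#'
#' Draws NB counts per sample over the shared synthetic gene panel, converts
#' to TPM (columns sum to one million per sample; unit effective lengths),
#' and assigns clinical covariates with declared frequencies: 45% low-risk
#' (age under 18 months, MYCN negative), 45% high-risk (age over 18 months,
#' MYCN positive), 10% stage 4S; 5% of samples get an unknown MYCN status.
#' A block of `markers_per_type` planted risk genes is elevated
#' `marker_log2fc` log2-fold in high-risk samples and recorded in the truth.
#'
#' @param config a [sim_config()].
#' @param tissue_panel if `TRUE`, generate a normal-tissue panel instead:
#'   samples cycle through a fixed tissue vocabulary (including brain
#'   tissues) and clinical covariates are omitted.
#' @return An object of class `bulk_cohort`: list with `tpm` and `counts`
#'   (sample-by-gene matrices), `covariates` (`data.frame`), and `truth`
#'   (planted `risk_genes` and the risk labels used for generation).
#' @export
simulate_bulk_cohort <- function(config, tissue_panel = FALSE) {
  validate_sim_config(config)
  if (config$n_bulk_samples < 2)
    stop("invalid sim_config: 'n_bulk_samples' must be at least 2")
  set.seed(config$seed + 2L)
  n <- config$n_bulk_samples
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  samples <- sprintf("bulk%04d", seq_len(n))

  base <- rlnorm(config$n_genes, meanlog = log(50), sdlog = 1)
  names(base) <- genes
  risk_genes <- genes[sample.int(config$n_genes, config$markers_per_type)]

  if (tissue_panel) {
    tissues <- c("brain cortex", "brain cerebellum", "liver", "kidney",
                 "lung", "skeletal muscle", "heart", "skin")
    covariates <- data.frame(sample = samples,
                             tissue = rep(tissues, length.out = n),
                             stringsAsFactors = FALSE)
    risk <- rep("none", n)
  } else {
    risk <- sample(c("low", "high", "4S"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.10))
    # age skews older and MYCN amplification commoner in high-risk disease,
    # but neither determines the risk group
    age <- round(ifelse(risk == "high", rgamma(n, 4, 1 / 9),
                        rgamma(n, 2, 1 / 5)), 1)
    mycn <- ifelse(risk == "high",
                   sample(c("pos", "neg"), n, replace = TRUE,
                          prob = c(0.4, 0.6)),
                   sample(c("pos", "neg"), n, replace = TRUE,
                          prob = c(0.03, 0.97)))
    mycn[sample.int(n, max(1, round(0.05 * n)))] <- "unknown"
    stage <- ifelse(risk == "4S", "4S",
                    ifelse(risk == "high",
                           sample(c("3", "4"), n, replace = TRUE),
                           sample(c("1", "2", "3"), n, replace = TRUE)))
    sites <- c("adrenal gland, NOS", "abdomen, NOS", "retroperitoneum",
               "kidney, NOS", "thoracic sympathetic chain",
               "mediastinum, NOS", "pelvis, NOS", "neck, NOS",
               "unknown primary site", "other ill-defined sites", "")
    covariates <- data.frame(
      sample = samples, age_months = round(age, 1), mycn_status = mycn,
      stage = stage, risk = risk,
      site_description = sample(sites, n, replace = TRUE,
                                prob = c(0.3, 0.1, 0.1, 0.05, 0.1,
                                         0.1, 0.05, 0.05, 0.05, 0.05, 0.05)),
      stringsAsFactors = FALSE)
  }

  phi <- config$nb_dispersion^2
  counts <- matrix(0L, nrow = n, ncol = config$n_genes,
                   dimnames = list(samples, genes))
  depth <- rpois(n, 5e5)
  for (i in seq_len(n)) {
    p <- base
    if (!tissue_panel && risk[i] == "high")
      p[risk_genes] <- p[risk_genes] * 2^config$marker_log2fc
    mu <- depth[i] * p / sum(p)
    counts[i, ] <- if (phi > 0) rnbinom(config$n_genes, mu = mu, size = 1 / phi)
                   else rpois(config$n_genes, mu)
  }
  tpm <- counts / rowSums(counts) * 1e6
  structure(list(tpm = tpm, counts = counts, covariates = covariates,
                 truth = list(risk_genes = risk_genes, risk = setNames(risk, samples),
                              log2fc = config$marker_log2fc)),
            class = "bulk_cohort")
}

#' Simulate a genome annotation with ordered transcription start sites
#'
#' Places the synthetic gene panel on one or two synthetic chromosomes
#' (10 Mb each) with strictly increasing, distinct TSS coordinates (0-based).
#' Optionally plants a "sympathoblast-high" region on chromosome 1 whose
#' resident genes are flagged in the output.
#'
#' @param config a [sim_config()].
#' @param n_chromosomes 1 or 2.
#' @param chrom_length length of each synthetic chromosome in bp.
#' @param planted_region optional `c(start, end)` in bp on `chr1`; genes with
#'   TSS inside it are flagged `in_planted_region`.
#' @param planted_genes optional gene ids forced to lie inside the planted
#'   region (e.g. one cell type's markers, giving the region a genuinely
#'   elevated expression topography for that type); all other genes are
#'   placed outside it.
#' @return A `data.frame` (class `genomic_annotation`) with columns
#'   `gene, chrom, tss, strand, in_planted_region`, rows ordered along the
#'   genome, and attributes `chrom_lengths` (named) and `planted_region`.
#' @export
simulate_genome_annotation <- function(config, n_chromosomes = 2,
                                       chrom_length = 1e7,
                                       planted_region = NULL,
                                       planted_genes = NULL) {
  validate_sim_config(config)
  stopifnot(n_chromosomes %in% 1:2)
  if (!is.null(planted_genes) && is.null(planted_region))
    stop("planted_genes requires a planted_region")
  set.seed(config$seed + 3L)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  if (!is.null(planted_genes) && !all(planted_genes %in% genes))
    stop("planted_genes must belong to the simulated gene panel")
  chrom <- sort(rep(paste0("chr", seq_len(n_chromosomes)),
                    length.out = config$n_genes))
  names(chrom) <- genes
  if (!is.null(planted_genes)) chrom[planted_genes] <- "chr1"

  draw_pos <- function(n, from, to, exclude = NULL) {
    pool <- seq.int(from, to - 1L)
    if (!is.null(exclude))
      pool <- pool[pool < exclude[1] | pool >= exclude[2]]
    sample(pool, n)
  }
  ann <- do.call(rbind, lapply(unique(chrom), function(ch) {
    g <- names(chrom)[chrom == ch]
    if (ch == "chr1" && !is.null(planted_region)) {
      inside <- intersect(g, planted_genes)
      outside <- setdiff(g, planted_genes)
      tss <- c(setNames(draw_pos(length(inside), planted_region[1],
                                 planted_region[2]), inside),
               setNames(draw_pos(length(outside), 0, chrom_length,
                                 exclude = planted_region), outside))
      tss <- tss[g]
    } else {
      tss <- setNames(sample.int(chrom_length, length(g)) - 1L, g)
    }
    data.frame(gene = g, chrom = ch, tss = as.integer(unname(tss)),
               strand = sample(c("+", "-"), length(g), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  ann <- ann[order(ann$chrom, ann$tss), ]
  rownames(ann) <- NULL
  ann$in_planted_region <- FALSE
  if (!is.null(planted_region)) {
    stopifnot(length(planted_region) == 2,
              planted_region[1] < planted_region[2])
    ann$in_planted_region <- ann$chrom == "chr1" &
      ann$tss >= planted_region[1] & ann$tss < planted_region[2]
  }
  attr(ann, "chrom_lengths") <- setNames(rep(chrom_length, n_chromosomes),
                                         paste0("chr", seq_len(n_chromosomes)))
  attr(ann, "planted_region") <- planted_region
  class(ann) <- c("genomic_annotation", "data.frame")
  ann
}
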