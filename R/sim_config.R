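#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults describe
#' a small but realistic fetal-adrenal-like experiment: a few hundred cells
#' per type, negative binomial counts with moderate overdispersion
#' (sqrt-dispersion 0.4, i.e. variance mu + 0.16 mu^2), markers elevated
#' two log2-fold, and shallow per-cell allele depth typical of 10x mRNA
#' coverage over a copy-number segment.
#'
#' @param seed integer RNG seed; the same seed reproduces every generated
#'   object bit-for-bit.
#' @param n_cell_types number of normal cell types (2..6), drawn in order
#'   from sympathoblast, chromaffin, SCP, bridge, leukocyte, mesenchyme.
#' @param cells_per_type cells simulated per normal type.
#' @param n_genes total genes.
#' @param markers_per_type planted marker genes per type.
#' @param marker_log2fc log2 fold elevation of a type's markers in that type
#'   over every other type. The default of 6 emulates near-binary lineage
#'   markers (SOX10-like on/off patterns); harder, smaller effects can be
#'   requested explicitly.
#' @param nb_dispersion square root of the NB overdispersion phi; counts have
#'   variance `mu + phi mu^2` with `phi = nb_dispersion^2`.
#' @param mean_umis mean per-cell sequencing depth (Poisson).
#' @param tumor_fraction fraction of cells that are tumor cells; tumor cells
#'   express the sympathoblast program (the state tumor cells adopt).
#' @param snps_per_segment heterozygous SNPs simulated per copy-number
#'   segment.
#' @param mean_allele_depth mean allele-informative reads per cell per
#'   segment (Poisson).
#' @param allele_error probability that a read reports the wrong haplotype.
#' @param n_bulk_samples samples in the synthetic bulk cohort.
#' @param qc_violation_rate fraction of cells planted with a QC violation
#'   (high mitochondrial fraction, high doublet score, low depth, or a
#'   positive cell-cycle score).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cell_types = 4L,
                       cells_per_type = 200L,
                       n_genes = 1000L,
                       markers_per_type = 20L,
                       marker_log2fc = 6,
                       nb_dispersion = 0.4,
                       mean_umis = 5000,
                       tumor_fraction = 0,
                       snps_per_segment = 10L,
                       mean_allele_depth = 20,
                       allele_error = 0.01,
                       n_bulk_samples = 100L,
                       qc_violation_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              marker_log2fc = marker_log2fc, nb_dispersion = nb_dispersion,
              mean_umis = mean_umis, tumor_fraction = tumor_fraction,
              snps_per_segment = as.integer(snps_per_segment),
              mean_allele_depth = mean_allele_depth,
              allele_error = allele_error,
              n_bulk_samples = as.integer(n_bulk_samples),
              qc_violation_rate = qc_violation_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  pos_int <- c("n_cell_types", "cells_per_type", "n_genes", "markers_per_type",
               "snps_per_segment", "n_bulk_samples")
  for (f in pos_int) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 1)
      stop("invalid sim_config: '", f, "' must be a positive integer")
  }
  pos_real <- c("mean_umis", "mean_allele_depth")
  for (f in pos_real) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v <= 0)
      stop("invalid sim_config: '", f, "' must be positive")
  }
  frac <- c("tumor_fraction", "allele_error", "qc_violation_rate")
  for (f in frac) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("invalid sim_config: '", f, "' must lie in [0, 1]")
  }
  if (cfg$nb_dispersion < 0)
    stop("invalid sim_config: 'nb_dispersion' must be non-negative")
  if (cfg$n_cell_types > length(cell_type_vocabulary()))
    stop("invalid sim_config: 'n_cell_types' must be at most ",
         length(cell_type_vocabulary()))
  # marker blocks are reserved for each type plus the tumor and control blocks
  if (cfg$markers_per_type * (cfg$n_cell_types + 2) > cfg$n_genes)
    stop("invalid sim_config: 'n_genes' too small for the requested markers")
  invisible(cfg)
}

cell_type_vocabulary <- function() {
  c("sympathoblast", "chromaffin", "SCP", "bridge", "leukocyte", "mesenchyme")
}
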