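#' Run the full synthetic-data workflow end to end
#'
#' Exercises every stage of the package on generated data with known ground
#' truth: simulate a reference and a tumor-bearing query, run QC (adrenal
#' preset with the high-resolution cluster rule for the reference, 10x
#' tumor preset for the query), normalize, train the elastic-net reference
#' model and score the query on the logit scale, genotype query cells from
#' allelic imbalance and classify clusters, derive tf-idf markers and
#' stringent marker sets, measure marker presence in a synthetic bulk
#' cohort with risk stratification, and run the genomic smoothing +
#' permutation test against a planted region. All randomness derives from
#' `config$seed`, so two runs with the same configuration write
#' byte-identical outputs.
#'
#' @param config a [sim_config()]; the defaults give a small but complete
#'   run.
#' @param out_dir optional directory; when given, all tables are serialized
#'   there (MTX/TSV/BED).
#' @return Invisibly, a list with every intermediate result.
#' @export
run_demo_pipeline <- function(config = sim_config(), out_dir = NULL) {
  validate_sim_config(config)

  ## reference: normal types + extrinsic control, with planted QC violations
  ref_cfg <- config
  ref_cfg$qc_violation_rate <- max(config$qc_violation_rate, 0.05)
  ref <- simulate_reference_counts(ref_cfg, include_control = TRUE,
                                   include_tumor = FALSE)
  ref_mat <- apply_qc(ref$matrix, qc_thresholds("adrenal"))
  ref_clean <- normalize_log(qc_survivors(ref_mat))

  ## query: tumor cells (sympathoblast state) among normal cells
  qry_cfg <- config
  qry_cfg$seed <- config$seed + 101L
  qry_cfg$tumor_fraction <- if (config$tumor_fraction > 0)
    config$tumor_fraction else 0.4
  qry <- simulate_reference_counts(qry_cfg, include_tumor = TRUE)
  qry_mat <- apply_qc(qry$matrix, qc_thresholds("tumor10x"))
  qry_clean <- normalize_log(qc_survivors(qry_mat))

  ## similarity scoring on the logit scale, no softmax
  ref_train <- subset_cells(ref_clean,
                            which(ref_clean$meta$cluster != "podocyte"))
  model <- train_reference_model(ref_train, ref_train$meta$cluster,
                                 alpha = 0.99, seed = config$seed)
  scores <- score_cells(model, qry_clean)

  ## genotyping from allelic imbalance over a one-copy loss and a gain
  segments <- copy_number_segments(
    chrom = c("chr1", "chr2"), start = c(1e6, 2e6), end = c(4e6, 6e6),
    major_cn = c(1L, 2L), minor_cn = c(0L, 1L))
  truth_q <- qry$truth
  truth_q$tumor_status_of <-
    truth_q$tumor_status_of[colnames(qry_clean$counts)]
  counts_tab <- simulate_allele_counts(qry_cfg, segments, truth_q)
  het <- attr(counts_tab, "snps")
  phased <- phase_snps(counts_tab, segments, het)
  post <- compute_posterior(counts_tab, phased, segments,
                            error_rate = config$allele_error + 0.005,
                            cells = colnames(qry_clean$counts))
  cluster_calls <- classify_clusters(
    post, setNames(qry_clean$meta$cluster, qry_clean$meta$cell))

  ## markers: tf-idf, stringent sets against the extrinsic control
  markers <- tfidf_markers(ref_clean)
  stringent <- stringent_cell_type_markers(ref_clean)

  ## bulk cohort: presence threshold, risk strata, extra-adrenal subset
  bulk <- simulate_bulk_cohort(config)
  risk <- stratify_risk_seqc(bulk)
  presence <- marker_presence_fraction(
    bulk, stringent[lengths(stringent) > 0],
    strata = setNames(risk$risk, risk$sample))
  extra_adrenal <- filter_extra_adrenal(bulk)
  bulk_de <- nb_glm_fixed_dispersion(bulk)

  ## genomic smoothing against a planted sympathoblast-high region
  ann <- simulate_genome_annotation(
    config, planted_region = c(2e6, 4e6),
    planted_genes = ref$truth$marker_genes$sympathoblast)
  symp_cells <- which(ref_clean$meta$cluster == "sympathoblast")
  chrom_cells <- which(ref_clean$meta$cluster == "chromaffin")
  w_a <- celltype_expression_weights(ref_clean, symp_cells)
  w_b <- celltype_expression_weights(ref_clean, chrom_cells)
  track_a <- smooth_expression_track(ann, w_a, cell_type = "sympathoblast")
  track_b <- smooth_expression_track(ann, w_b, cell_type = "chromaffin")
  region <- define_breakpoint_region("chr1", 3e6, 1e6,
                                     attr(ann, "chrom_lengths"))
  region_test <- region_difference_test(track_a, track_b, region,
                                        n_permutations = 1000,
                                        seed = config$seed)

  out <- list(reference = ref_mat, reference_clean = ref_clean,
              query = qry_mat, query_clean = qry_clean,
              model = model, scores = scores, segments = segments,
              phased = phased, posteriors = post,
              cluster_calls = cluster_calls, markers = markers,
              stringent_markers = stringent, bulk = bulk, risk = risk,
              presence = presence, extra_adrenal = extra_adrenal,
              bulk_de = bulk_de, annotation = ann,
              tracks = list(sympathoblast = track_a,
                            chromaffin = track_b),
              region_test = region_test,
              truth = list(reference = ref$truth, query = qry$truth,
                           bulk = bulk$truth))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_matrix(ref_mat, file.path(out_dir, "reference"))
    write_tsv(qc_report(ref_mat), file.path(out_dir, "qc_reference.tsv"))
    write_tsv(qc_report(qry_mat), file.path(out_dir, "qc_query.tsv"))
    write_reference_model(model, file.path(out_dir, "reference_model.tsv"))
    sc <- data.frame(cell = rownames(scores$cell_logits),
                     scores$cell_logits, check.names = FALSE)
    write_tsv(sc, file.path(out_dir, "similarity_logits.tsv"))
    write_bed(segments, file.path(out_dir, "segments.bed"))
    write_tsv(post, file.path(out_dir, "genotype_posteriors.tsv"))
    write_tsv(cluster_calls, file.path(out_dir, "cluster_calls.tsv"))
    write_tsv(markers, file.path(out_dir, "markers.tsv"))
    write_tsv(presence$per_gene, file.path(out_dir, "bulk_presence.tsv"))
    write_tsv(bulk_de, file.path(out_dir, "bulk_de.tsv"))
    write_tsv(as.data.frame(track_a), file.path(out_dir,
                                                "track_sympathoblast.tsv"))
    write_tsv(data.frame(observed_diff = region_test$observed_diff,
                         p = region_test$p,
                         n_permutations = region_test$n_permutations),
              file.path(out_dir, "region_test.tsv"))
  }
  invisible(out)
}
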