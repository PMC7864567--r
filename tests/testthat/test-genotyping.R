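seg_loss <- function() copy_number_segments("chr1", 0L, 1e6, 1L, 0L)

test_that("phasing follows the pooled majority with a flagged tie-break", {
  seg <- seg_loss()
  counts <- data.frame(cell = c("a", "b", "a", "b"),
                       chrom = "chr1", pos = c(100, 100, 200, 200),
                       ref_count = c(5, 5, 25, 25),
                       alt_count = c(50, 40, 25, 25))
  het <- data.frame(chrom = "chr1", pos = c(100, 200),
                    ref_allele = "A", alt_allele = "G")
  ph <- phase_snps(counts, seg, het)
  expect_identical(ph$major_is_alt, c(TRUE, FALSE))
  expect_equal(ph$phase_confidence, c(90 / 100, 0.5))
  expect_identical(ph$tied, c(FALSE, TRUE))

  # SNPs outside every segment are skipped with a warning
  het2 <- rbind(het, data.frame(chrom = "chr1", pos = 2e6,
                                ref_allele = "A", alt_allele = "G"))
  expect_warning(ph2 <- phase_snps(counts, seg, het2), "outside")
  expect_identical(nrow(ph2), 2L)
})

test_that("phasing recovers the true haplotype from simulated tumors", {
  cfg <- sim_config(seed = 21, n_cell_types = 1, cells_per_type = 50,
                    n_genes = 120, markers_per_type = 10,
                    tumor_fraction = 0.8, snps_per_segment = 30,
                    mean_allele_depth = 60, allele_error = 0.01)
  sim <- simulate_reference_counts(cfg, include_tumor = TRUE)
  seg <- seg_loss()
  ac <- simulate_allele_counts(cfg, seg, sim$truth)
  snps <- attr(ac, "snps")
  ph <- phase_snps(ac, seg, snps)
  truth <- snps$major_is_alt[match(paste(ph$chrom, ph$pos),
                                   paste(snps$chrom, snps$pos))]
  expect_gte(mean(ph$major_is_alt == truth), 0.95)
})

test_that("posterior matches the closed-form Bayes evaluation", {
  seg <- seg_loss()  # expected major fraction 1, clipped to 0.99
  ph <- data.frame(chrom = "chr1", pos = 500, major_is_alt = FALSE,
                   segment = 1)
  p10 <- compute_posterior(
    data.frame(cell = "c", chrom = "chr1", pos = 500,
               ref_count = 10, alt_count = 0), ph, seg,
    error_rate = 0.01, prior_tumor = 0.5)
  expect_equal(p10$posterior_tumor, 0.99^10 / (0.99^10 + 0.5^10),
               tolerance = 1e-12)
  expect_identical(p10$call, "definitive_tumor")

  p5 <- compute_posterior(
    data.frame(cell = "c", chrom = "chr1", pos = 500,
               ref_count = 5, alt_count = 5), ph, seg,
    error_rate = 0.01, prior_tumor = 0.5)
  expect_equal(p5$posterior_tumor,
               (0.99^5 * 0.01^5) / (0.99^5 * 0.01^5 + 0.5^10),
               tolerance = 1e-10)
  expect_identical(p5$call, "definitive_normal")

  # a cell with no informative reads keeps the prior: logit exactly 0
  p0 <- compute_posterior(
    data.frame(cell = "c", chrom = "chr1", pos = 500,
               ref_count = 1, alt_count = 0)[0, ], ph, seg,
    cells = "ghost")
  expect_equal(p0$posterior_tumor, 0.5)
  expect_equal(p0$logit, 0)
  expect_identical(p0$call, "uninformative")
})

test_that("posterior is monotone in the major count and label-swap invariant", {
  seg <- copy_number_segments("chr1", 0L, 1e6, 3L, 2L)  # f = 0.6
  ph <- data.frame(chrom = "chr1", pos = 500, major_is_alt = FALSE,
                   segment = 1)
  post_k <- vapply(0:20, function(k) {
    compute_posterior(data.frame(cell = "c", chrom = "chr1", pos = 500,
                                 ref_count = k, alt_count = 20 - k),
                      ph, seg)$posterior_tumor
  }, numeric(1))
  expect_true(all(diff(post_k) >= 0))

  # swapping ref/alt everywhere while flipping major_is_alt changes nothing
  set.seed(1)
  counts <- data.frame(cell = rep(c("a", "b"), each = 3),
                       chrom = "chr1", pos = rep(c(100, 300, 700), 2),
                       ref_count = rpois(6, 5), alt_count = rpois(6, 3))
  ph3 <- data.frame(chrom = "chr1", pos = c(100, 300, 700),
                    major_is_alt = c(TRUE, FALSE, TRUE), segment = 1)
  swapped <- counts
  swapped$ref_count <- counts$alt_count
  swapped$alt_count <- counts$ref_count
  ph3s <- ph3; ph3s$major_is_alt <- !ph3$major_is_alt
  expect_equal(compute_posterior(counts, ph3, seg)$posterior_tumor,
               compute_posterior(swapped, ph3s, seg)$posterior_tumor)
})

test_that("parameter validation rejects out-of-range error and prior", {
  seg <- seg_loss()
  ph <- data.frame(chrom = "chr1", pos = 1, major_is_alt = FALSE,
                   segment = 1)
  cc <- data.frame(cell = "c", chrom = "chr1", pos = 1,
                   ref_count = 1, alt_count = 0)
  expect_error(compute_posterior(cc, ph, seg, error_rate = 0.6),
               "error_rate")
  expect_error(compute_posterior(cc, ph, seg, prior_tumor = 1), "prior")
})

test_that("cluster verdicts require a strict definitive-tumor majority", {
  mk_post <- function(n_t, n_n, n_u, cluster) {
    p <- c(rep(0.999, n_t), rep(0.001, n_n), rep(0.5, n_u))
    structure(data.frame(
      cell = sprintf("%s_%02d", cluster, seq_along(p)),
      k_major = 1, n_total = 1, posterior_tumor = p,
      logit = log(p / (1 - p)),
      call = ifelse(p > 0.99, "definitive_tumor",
                    ifelse(p < 0.01, "definitive_normal",
                           "uninformative")),
      stringsAsFactors = FALSE),
      class = c("genotype_posterior", "data.frame"))
  }
  post <- rbind(mk_post(30, 5, 2, "A"), mk_post(0, 0, 8, "B"),
                mk_post(7, 7, 0, "C"))
  class(post) <- c("genotype_posterior", "data.frame")
  clusters <- setNames(sub("_.*", "", post$cell), post$cell)
  verdicts <- classify_clusters(post, clusters)
  expect_identical(setNames(verdicts$verdict, verdicts$cluster),
                   c(A = "tumor", B = "not_tumor", C = "not_tumor"))
  expect_equal(verdicts$mean_posterior[verdicts$cluster == "B"], 0.5)
})
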