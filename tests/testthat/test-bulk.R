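toy_cohort <- function(tpm, covariates = NULL, counts = NULL) {
  if (is.null(covariates))
    covariates <- data.frame(sample = rownames(tpm),
                             stringsAsFactors = FALSE)
  structure(list(tpm = tpm, counts = counts, covariates = covariates,
                 truth = NULL), class = "bulk_cohort")
}

test_that("the presence threshold recovers the mode of log2(TPM)", {
  set.seed(10)
  v <- 2^rnorm(1e5, mean = 2, sd = 0.5)
  tpm <- matrix(v, nrow = 100,
                dimnames = list(paste0("s", 1:100), paste0("g", 1:1000)))
  expect_lt(abs(presence_threshold(tpm) - 2), 0.1)

  # bimodal with the taller mode low: the threshold sits at the low mode
  v2 <- 2^c(rnorm(6e4, 1, 0.3), rnorm(4e4, 4, 0.3))
  tpm2 <- matrix(v2, nrow = 100)
  expect_lt(abs(presence_threshold(tpm2) - 1), 0.15)

  # point mass: threshold equals the value, and nothing is "present"
  # under the strict inequality
  tpm3 <- matrix(8, nrow = 20, ncol = 10,
                 dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
  th <- presence_threshold(tpm3, min_positive = 100)
  expect_equal(th, 3)
  expect_true(all(!(log2(tpm3) > th)))

  expect_error(presence_threshold(matrix(0, 20, 20)), "positive")
  # order invariance: permuting samples leaves the threshold unchanged
  expect_equal(presence_threshold(tpm[sample(100), ]),
               presence_threshold(tpm))
})

test_that("marker presence fractions match a hand count", {
  tpm <- rbind(s1 = c(gA = 8, gB = 1, gC = 8),
               s2 = c(gA = 8, gB = 8, gC = 8),
               s3 = c(gA = 8, gB = 1, gC = 1),
               s4 = c(gA = 8, gB = 1, gC = 1))
  cohort <- toy_cohort(tpm)
  res <- marker_presence_fraction(
    cohort, list(set1 = c("gA", "gB", "gC", "gMissing")), threshold = 2)
  pg <- res$per_gene
  expect_equal(setNames(pg$fraction_present, pg$gene),
               c(gA = 1, gB = 0.25, gC = 0.5))
  expect_identical(res$missing$set1, "gMissing")
  expect_equal(res$summary$median, 0.5)

  # stratified fractions count within each stratum
  res2 <- marker_presence_fraction(
    cohort, list(set1 = "gB"), threshold = 2,
    strata = c(s1 = "x", s2 = "y", s3 = "x", s4 = "y"))
  pg2 <- res2$per_gene
  expect_equal(pg2$fraction_present[pg2$stratum == "x"], 0)
  expect_equal(pg2$fraction_present[pg2$stratum == "y"], 0.5)
})

test_that("risk stratification applies the two printed rules exactly", {
  cov <- data.frame(
    sample = paste0("s", 1:7),
    age_months = c(10, 30, 5, 10, 30, NA, 10),
    mycn_status = c("neg", "pos", "pos", "neg", "neg", "neg", "unknown"),
    stage = c("2", "4", "4S", "4S", "3", "2", "2"),
    stringsAsFactors = FALSE)
  cohort <- toy_cohort(matrix(1, 7, 2,
                              dimnames = list(cov$sample, c("g1", "g2"))),
                       covariates = cov)
  res <- stratify_risk_seqc(cohort)
  expect_identical(res$risk,
                   c("low", "high", "unclassified", "unclassified",
                     "unclassified", "unclassified", "unclassified"))
  expect_match(res$reason[3], "4S")
  expect_match(res$reason[6], "missing")
  expect_match(res$reason[7], "missing")
})

test_that("extra-adrenal filtering removes stop-word and empty sites", {
  cov <- data.frame(
    sample = paste0("s", 1:6),
    site_description = c("adrenal gland, NOS", "",
                         "thoracic sympathetic chain",
                         "Retroperitoneum", "pelvis, NOS", NA),
    stringsAsFactors = FALSE)
  cohort <- toy_cohort(matrix(1, 6, 2,
                              dimnames = list(cov$sample, c("g1", "g2"))),
                       covariates = cov)
  expect_identical(filter_extra_adrenal(cohort), c("s3", "s5"))
})

test_that("fixed-dispersion NB DE needs counts and a full-rank design", {
  cfg <- sim_config(seed = 41, n_bulk_samples = 60, n_genes = 300,
                    markers_per_type = 15, marker_log2fc = 2)
  bulk <- simulate_bulk_cohort(cfg)
  tpm_only <- bulk
  tpm_only$counts <- NULL
  expect_error(nb_glm_fixed_dispersion(tpm_only), "counts")

  aliased <- bulk
  aliased$covariates$mycn_status <-
    ifelse(aliased$truth$risk == "high", "pos", "neg")
  aliased$covariates$age_months <- 1
  expect_error(nb_glm_fixed_dispersion(aliased), "rank deficient")
})

test_that("fixed-dispersion NB DE approaches Poisson as dispersion -> 0", {
  set.seed(5)
  n <- 40
  n_genes <- 200
  risk <- rep(c("low", "high"), each = n / 2)
  mu <- matrix(100, nrow = n, ncol = n_genes,
               dimnames = list(paste0("s", 1:n),
                               sprintf("g%03d", 1:n_genes)))
  mu[risk == "high", "g001"] <- 300  # planted 3x effect
  counts <- matrix(rpois(length(mu), mu), nrow = n, dimnames = dimnames(mu))
  cov <- data.frame(sample = rownames(counts),
                    age_months = runif(n, 1, 40),
                    mycn_status = "neg", risk = risk,
                    stringsAsFactors = FALSE)
  cohort <- toy_cohort(counts / rowSums(counts) * 1e6, cov, counts)
  res <- nb_glm_fixed_dispersion(cohort, sqrt_dispersion = 1e-4)
  # near the Poisson limit the planted coefficient matches a Poisson GLM
  rf <- factor(risk, levels = c("low", "high"))
  ref_fit <- glm(counts[, "g001"] ~ cov$age_months + rf,
                 family = poisson, offset = log(rowSums(counts)))
  expect_equal(res$log2fc[res$gene == "g001"],
               unname(coef(ref_fit)["rfhigh"]) / log(2),
               tolerance = 0.05)
  expect_true(res$significant[res$gene == "g001"])
  # a gene with identical group means stays near zero and non-significant
  expect_lt(abs(res$log2fc[res$gene == "g002"]), 0.3)
  expect_false(res$significant[res$gene == "g002"])
})

test_that("fetal cancer transcripts are filtered then ranked ascending", {
  stats_a <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    cancer_detect_fraction = c(0.9, 0.4, 0.8, 0.9),
    max_other_cluster_fraction = c(0.1, 0.1, 0.1, 0.1))
  stats_b <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    cancer_detect_fraction = c(0.8, 0.9, 0.7, 0.9),
    max_other_cluster_fraction = c(0.05, 0.05, 0.30, 0.05))
  medulla <- c(g1 = 0.5, g2 = 0.6, g3 = 0.7, g4 = 0.05)
  tpm <- rbind(b1 = c(g1 = 10, g2 = 10, g3 = 10, g4 = 10),
               n1 = c(g1 = 7, g2 = 1, g3 = 1, g4 = 1),
               n2 = c(g1 = 1, g2 = 1, g3 = 3, g4 = 1))
  panel <- toy_cohort(tpm, data.frame(
    sample = rownames(tpm), tissue = c("brain cortex", "liver", "lung"),
    stringsAsFactors = FALSE))
  # g2 fails the 50% cancer-cell rule in dataset A, g3 the 20% other-cluster
  # rule in dataset B, g4 the 10% medulla rule; g1 survives
  res <- fetal_cancer_transcripts(list(stats_a, stats_b), medulla, panel)
  expect_identical(res$gene, "g1")
  # ranking: lower non-brain expression first
  stats_a2 <- stats_a; stats_a2$cancer_detect_fraction <- 0.9
  stats_b2 <- stats_b; stats_b2$max_other_cluster_fraction <- 0.05
  medulla2 <- c(g1 = 0.5, g2 = 0.6, g3 = 0.7, g4 = 0.5)
  res2 <- fetal_cancer_transcripts(list(stats_a2, stats_b2), medulla2,
                                   panel)
  nb_mean <- colMeans(log2(tpm[2:3, res2$gene] + 1))
  expect_identical(res2$gene, names(sort(nb_mean)))
})
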