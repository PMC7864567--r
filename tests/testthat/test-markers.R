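three_cluster_cm <- function(seed = 1, n_genes = 20, per_cluster = 12) {
  set.seed(seed)
  n <- 3 * per_cluster
  counts <- matrix(rbinom(n_genes * n, 1, 0.3) * rpois(n_genes * n, 3),
                   nrow = n_genes)
  clusters <- rep(c("k1", "k2", "k3"), each = per_cluster)
  # g001: expressed everywhere; g002: private to k1
  counts[1, ] <- 1
  counts[2, ] <- ifelse(clusters == "k1", 5, 0)
  make_cm(counts, cluster = clusters)
}

test_that("tf-idf and hypergeometric p match a direct-summation oracle", {
  cm <- three_cluster_cm()
  res <- tfidf_markers(cm, return_all = TRUE)
  bin <- as.matrix(cm$counts) > 0
  N <- ncol(bin)
  for (r in sample(nrow(res), 60)) {
    row <- res[r, ]
    idx <- cm$meta$cluster == row$cluster
    n_in <- sum(bin[row$gene, idx])
    m <- sum(bin[row$gene, ])
    expect_equal(row$tf, n_in / sum(idx))
    expect_equal(row$global_rate, m / N)
    expect_equal(row$tfidf,
                 if (n_in == 0 || m == N) 0 else
                   (n_in / sum(idx)) * log(N / m))
    # oracle: direct summation over the hypergeometric support
    support <- max(0, sum(idx) + m - N):min(sum(idx), m)
    p_direct <- sum(vapply(support[support >= n_in], function(k)
      choose(m, k) * choose(N - m, sum(idx) - k) / choose(N, sum(idx)),
      numeric(1)))
    expect_equal(row$p_raw, p_direct, tolerance = 1e-12)
  }
  # a gene expressed in every cell can never be a marker
  expect_true(all(res$tfidf[res$gene == "g001"] == 0))
  # the private gene tops its cluster
  r2 <- res[res$gene == "g002" & res$cluster == "k1", ]
  expect_equal(r2$tf, 1)
  expect_gt(r2$tfidf, 1)
})

test_that("the tf-idf cutoff identity holds on a parameter grid", {
  # a gene passes cutoff t iff global_rate < exp(-t / tf)
  t_cut <- 1
  tf <- seq(0.05, 1, length.out = 40)
  gr <- seq(0.01, 1, length.out = 40)
  for (a in tf) for (b in gr) {
    tfidf <- a * log(1 / b)
    expect_identical(tfidf > t_cut, b < exp(-t_cut / a))
  }
})

test_that("stringent markers honor the cross-cluster expression filter", {
  per <- 20
  clusters <- rep(c("target", "otherA", "otherB", "podocyte"), each = per)
  n <- length(clusters)
  counts <- matrix(rbinom(30 * n, 1, 0.10) * 2, nrow = 30)
  # gA: strong in target, silent elsewhere -> kept
  counts[1, ] <- ifelse(clusters == "target", 4, 0)
  # gB: strong in target but expressed in 25% of otherA -> excluded
  counts[2, ] <- 0
  counts[2, clusters == "target"] <- 4
  counts[2, which(clusters == "otherA")[1:5]] <- 1
  cm <- make_cm(counts, cluster = clusters)
  sets <- stringent_cell_type_markers(cm)
  expect_true("g001" %in% sets$target)
  expect_false("g002" %in% sets$target)
  expect_false("podocyte" %in% names(sets))
  # a missing control population warns but proceeds
  cm2 <- subset_cells(cm, which(clusters != "podocyte"))
  expect_warning(stringent_cell_type_markers(cm2), "control")
})

test_that("planted markers are recovered exactly at a large effect size", {
  cfg <- sim_config(seed = 31, n_cell_types = 4, cells_per_type = 80,
                    n_genes = 1000, markers_per_type = 20,
                    marker_log2fc = 6, mean_umis = 2000)
  sim <- simulate_reference_counts(cfg, include_control = TRUE)
  cm <- normalize_log(sim$matrix)
  sets <- stringent_cell_type_markers(cm)
  for (t in setdiff(names(sets), "podocyte"))
    expect_setequal(sets[[t]], sim$truth$marker_genes[[t]])
})

test_that("tumor marker merging averages tf-idf and filters leukocytes", {
  a <- data.frame(gene = c("g1", "g2", "g3"), tfidf = c(1.0, 0.80, 0.86))
  b <- data.frame(gene = c("g1", "g2"), tfidf = c(0.8, 0.95))
  lf <- c(g1 = 0.30, g2 = 0.10, g3 = 0.10)
  # g1: mean 0.9 > 0.85 but 30% of leukocytes express it -> dropped
  # g2: mean 0.875 > 0.85, leukocyte-quiet -> kept
  # g3: single list, 0.86 > 0.85 -> kept
  expect_setequal(merge_tumor_markers(a, b, leukocyte_fraction = lf),
                  c("g2", "g3"))
  # without the leukocyte filter g1 stays
  expect_setequal(merge_tumor_markers(a, b), c("g1", "g2", "g3"))
  # boundary: an average exactly at the cutoff is excluded
  d <- data.frame(gene = "g9", tfidf = 0.85)
  expect_length(merge_tumor_markers(d, d[0, ]), 0)
})

test_that("rank-sum DE prefilters on detection and matches hand ranks", {
  # gene detected in 10% of both groups is excluded before testing
  set.seed(2)
  counts <- matrix(rpois(40 * 20, 2) + 1, nrow = 40)
  counts[1, ] <- rbinom(20, 1, 0.10)
  cm <- normalize_log(make_cm(counts))
  cells <- colnames(cm$counts)
  res <- ranksum_de(cm, cells[1:10], cells[11:20], return_all = TRUE)
  expect_false("g001" %in% res$gene)

  # 5-vs-5 toy with hand-computed rank-sum statistic W = 10
  counts2 <- rbind(a = c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10),
                   b = rep(1, 10), c = rep(2, 10))
  cm2 <- make_cm(counts2)
  cm2$logcounts <- cm2$counts  # identity transform keeps the ranks explicit
  cells2 <- colnames(cm2$counts)
  res2 <- ranksum_de(cm2, cells2[1:5], cells2[6:10], return_all = TRUE)
  expect_equal(res2$statistic[res2$gene == "a"], 10)
  # constant genes are reported with p = 1
  expect_equal(res2$p_raw[res2$gene %in% c("b", "c")], c(1, 1))

  # permuted labels within one population: no discoveries at FDR 0.01
  cfg <- sim_config(seed = 32, n_cell_types = 2, cells_per_type = 60,
                    n_genes = 400, mean_umis = 1500)
  sim <- simulate_reference_counts(cfg)
  cm3 <- normalize_log(sim$matrix)
  one_type <- cm3$meta$cell[cm3$meta$cluster == "sympathoblast"]
  set.seed(1)
  one_type <- sample(one_type)
  null_res <- ranksum_de(cm3, one_type[1:30], one_type[31:60])
  expect_identical(nrow(null_res), 0L)
})

test_that("genewise NB DE recovers planted effects and controls error", {
  cfg <- sim_config(seed = 33, n_cell_types = 2, cells_per_type = 100,
                    n_genes = 600, markers_per_type = 20,
                    marker_log2fc = 2, mean_umis = 2000)
  sim <- simulate_reference_counts(cfg)
  cm <- sim$matrix
  a <- cm$meta$cell[cm$meta$cluster == "sympathoblast"]
  b <- cm$meta$cell[cm$meta$cluster == "chromaffin"]
  res <- nb_de_genewise(cm, a, b)
  planted <- res[match(sim$truth$marker_genes$sympathoblast, res$gene), ]
  expect_gte(mean(abs(planted$log2fc - 2) <= 0.3), 0.9)

  # null split within one population: raw type-I error near nominal
  set.seed(3)
  a_perm <- sample(a)
  null_res <- nb_de_genewise(cm, a_perm[1:50], a_perm[51:100])
  t1 <- mean(null_res$p_raw < 0.05, na.rm = TRUE)
  expect_gte(t1, 0.02)
  expect_lte(t1, 0.08)

  # degenerate inputs: all-zero genes get a defined status, small groups
  # are pushed toward the fixed-dispersion route
  cm0 <- cm
  cm0$counts[5, ] <- 0
  res0 <- nb_de_genewise(cm0, a[1:20], b[1:20])
  expect_identical(res0$status[5], "all_zero")
  expect_true(is.na(res0$p_raw[5]))
  expect_error(nb_de_genewise(cm, a[1:5], b[1:5]), "fixed")
})

test_that("hypergeometric enrichment matches combinatorial evaluation", {
  universe <- paste0("u", 1:20)
  hits <- universe[1:10]
  markers <- universe[1:4]
  res <- hypergeometric_enrichment(hits, markers, universe)
  expect_identical(res$overlap, 4L)
  expect_equal(res$p, choose(10, 4) / choose(20, 4), tolerance = 1e-12)

  # hits = universe makes any overlap certain
  expect_equal(hypergeometric_enrichment(universe, markers, universe)$p, 1)

  # zero overlap: p is one minus the positive-overlap mass, by enumeration
  res0 <- hypergeometric_enrichment(universe[11:14], universe[1:3],
                                    universe[1:14])
  mass <- sum(vapply(1:3, function(k)
    choose(3, k) * choose(11, 4 - k) / choose(14, 4), numeric(1)))
  expect_equal(res0$p, 1, tolerance = 1e-12)
  expect_equal(1 - mass,
               choose(11, 4) / choose(14, 4), tolerance = 1e-12)

  expect_error(hypergeometric_enrichment("a", "a", character()), "universe")
  expect_error(hypergeometric_enrichment("zz", markers, universe), "subset")
})
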