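# Builders for small in-code fixtures used across the suite.

# cell_matrix from a dense matrix plus optional metadata columns
make_cm <- function(counts, ...) {
  meta_cols <- list(...)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  meta <- data.frame(cell = colnames(counts), stringsAsFactors = FALSE)
  for (nm in names(meta_cols)) meta[[nm]] <- meta_cols[[nm]]
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE), meta)
}

# a cell with an exact number of detected genes and total UMIs, as one
# column of a dense gene-by-cell matrix with n_genes rows
cell_column <- function(n_genes, genes_detected, umis) {
  stopifnot(genes_detected <= n_genes, umis >= genes_detected)
  col <- numeric(n_genes)
  if (genes_detected > 0) {
    col[seq_len(genes_detected)] <- 1
    col[1] <- umis - genes_detected + 1
  }
  col
}

# crafted 12-cell QC fixture exercising every threshold boundary of the
# adrenal preset; expected survivors: c01 c02 c04 c06 c08 c10
qc_fixture <- function() {
  spec <- list(
    #        genes  umis  mito  doublet    s     g2m  cluster
    c01 = list(500, 2000, 0.10, 0.10, -1.0, -1.0, "A"),
    c02 = list(500, 2000, 0.30, 0.10, -1.0, -1.0, "A"),  # mito boundary
    c03 = list(500, 2000, 0.31, 0.10, -1.0, -1.0, "B"),  # mito fail
    c04 = list(300, 1300, 0.10, 0.10, -1.0, -1.0, "A"),  # genes boundary
    c05 = list(299, 1500, 0.10, 0.10, -1.0, -1.0, "B"),  # genes fail
    c06 = list(500, 1000, 0.10, 0.10, -1.0, -1.0, "A"),  # umis boundary
    c07 = list(400,  999, 0.10, 0.10, -1.0, -1.0, "B"),  # umis fail
    c08 = list(500, 2000, 0.10, 0.20, -1.0, -1.0, "A"),  # doublet boundary
    c09 = list(500, 2000, 0.10, 0.21, -1.0, -1.0, "A"),  # doublet fail
    c10 = list(500, 2000, 0.10, 0.10,  0.0,  0.0, "A"),  # cycling boundary
    c11 = list(500, 2000, 0.10, 0.10,  0.01, -1.0, "A"), # cycling fail
    c12 = list(500, 2000, 0.10, 0.10, -1.0, -1.0, "B"))  # cluster-rule fail
  n_genes <- 600
  counts <- vapply(spec, function(s) cell_column(n_genes, s[[1]], s[[2]]),
                   numeric(n_genes))
  colnames(counts) <- names(spec)
  make_cm(counts,
          mito_fraction = vapply(spec, function(s) s[[3]], numeric(1)),
          doublet_score = vapply(spec, function(s) s[[4]], numeric(1)),
          s_score = vapply(spec, function(s) s[[5]], numeric(1)),
          g2m_score = vapply(spec, function(s) s[[6]], numeric(1)),
          cluster = vapply(spec, function(s) s[[7]], character(1)))
}

# brute-force per-cell evaluation of the adrenal QC rule set, written
# independently of the package's flagging code
brute_force_survivors <- function(cm, th = list(mito = 0.30, genes = 300,
                                                umis = 1000, doublet = 0.2,
                                                cluster = 0.5)) {
  m <- cm$meta
  indiv <- m$mito_fraction > th$mito | m$n_genes_detected < th$genes |
    m$n_umis < th$umis | m$doublet_score > th$doublet
  frac <- tapply(indiv, m$cluster, mean)
  clustered <- frac[as.character(m$cluster)] > th$cluster
  cycling <- m$s_score > 0 | m$g2m_score > 0
  m$cell[!(indiv | clustered | cycling)]
}

# brute-force Bayes posterior: direct product of binomial pmfs, no logs
brute_posterior <- function(k, n, f, error_rate = 0.01, prior = 0.5) {
  fc <- pmin(pmax(f, error_rate), 1 - error_rate)
  lt <- prod(dbinom(k, n, fc))
  ln <- prod(dbinom(k, n, 0.5))
  prior * lt / (prior * lt + (1 - prior) * ln)
}
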