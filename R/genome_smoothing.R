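#' Gaussian-kernel-smoothed expression track along the genome
#'
#' Places each gene's weight (typically the mean library-size-normalized
#' expression of one cell type) at its transcription start site and smooths
#' with a Gaussian kernel: `track(x) = sum_g w_g * phi_sigma(x - tss_g)`
#' with `sigma = bandwidth` (default 200 kb), evaluated on a regular grid.
#' This is roughly a running mean of normalized expression along each
#' chromosome; the track integrates to (approximately) the total weight.
#'
#' @param annotation a [simulate_genome_annotation()]-style table
#'   (`gene, chrom, tss`) with a `chrom_lengths` attribute (or supply
#'   `chrom_lengths`).
#' @param weights named non-negative per-gene weights; genes must appear in
#'   the annotation. Genes of the annotation missing from `weights` get 0.
#' @param bandwidth kernel standard deviation in bp (default 200,000).
#' @param grid_step grid spacing in bp (default `bandwidth / 10`).
#' @param chrom_lengths named chromosome lengths; defaults to the
#'   annotation attribute.
#' @param cell_type optional label stored on the track.
#' @return `data.frame` of class `genomic_track` with columns
#'   `chrom, pos, value` and attributes `bandwidth`, `grid_step`,
#'   `chrom_lengths`, `cell_type`.
#' @export
smooth_expression_track <- function(annotation, weights, bandwidth = 2e5,
                                    grid_step = bandwidth / 10,
                                    chrom_lengths = NULL,
                                    cell_type = NA_character_) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(annotation)))
  if (is.null(chrom_lengths))
    chrom_lengths <- attr(annotation, "chrom_lengths")
  if (is.null(chrom_lengths)) stop("chrom_lengths required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (is.null(names(weights))) stop("weights must be named by gene")
  if (!all(names(weights) %in% annotation$gene))
    stop("weights contain genes absent from the annotation")
  w <- setNames(numeric(nrow(annotation)), annotation$gene)
  w[names(weights)] <- weights

  track <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    grid <- seq(0, chrom_lengths[[ch]], by = grid_step)
    on_ch <- annotation$chrom == ch
    vals <- numeric(length(grid))
    if (any(on_ch)) {
      tss <- annotation$tss[on_ch]
      wc <- w[annotation$gene[on_ch]]
      nz <- wc > 0
      if (any(nz)) {
        # genes x grid kernel matrix; fine at track resolution
        vals <- as.numeric(
          crossprod(wc[nz],
                    vapply(grid, function(x)
                      dnorm(x - tss[nz], sd = bandwidth),
                      numeric(sum(nz)))))
      }
    }
    data.frame(chrom = ch, pos = grid, value = vals,
               stringsAsFactors = FALSE)
  }))
  rownames(track) <- NULL
  structure(track, bandwidth = bandwidth, grid_step = grid_step,
            chrom_lengths = chrom_lengths, cell_type = cell_type,
            class = c("genomic_track", "data.frame"))
}

#' Mean library-size-normalized expression per gene for one cell type
#'
#' The per-cell-type weights used for [smooth_expression_track()]: the mean
#' over the type's cells of depth-normalized counts (counts divided by the
#' cell total). The mean (rather than the sum) keeps tracks comparable
#' between cell types with different cell numbers.
#'
#' @param x a [cell_matrix()].
#' @param cells the cell ids (or indices) of the cell type.
#' @return Named per-gene numeric weights.
#' @export
celltype_expression_weights <- function(x, cells) {
  stopifnot(is(x, "cell_matrix"))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  if (anyNA(cells)) stop("unknown cell id")
  m <- x$counts[, cells, drop = FALSE]
  depth <- Matrix::colSums(m)
  if (any(depth == 0)) stop("cells with zero depth in the selection")
  as.numeric(Matrix::rowMeans(m %*% Matrix::Diagonal(x = 1 / depth))) |>
    setNames(rownames(x$counts))
}

#' Recurrently gained/lost regions from binned copy-number calls
#'
#' Given per-sample gain/loss calls on a shared genome binning, finds the
#' maximal runs of consecutive bins in which the number of altered samples
#' reaches `min_samples` (a bin at exactly the threshold qualifies),
#' separately for gains and losses.
#'
#' @param bins `data.frame` with `chrom, start, end`, sorted and
#'   non-overlapping within each chromosome.
#' @param calls sample-by-bin integer matrix with values -1 (loss),
#'   0 (neutral), 1 (gain); columns aligned with `bins` rows.
#' @param min_samples recurrence threshold (default 200).
#' @return `data.frame` with `chrom, start, end, type` (gain/loss) and
#'   `max_samples` (the run's peak altered-sample count).
#' @export
define_recurrent_regions <- function(bins, calls, min_samples = 200) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  if (ncol(calls) != nrow(bins))
    stop("calls must have one column per bin")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE) ||
        any(b$start[-1] < b$end[-nrow(b)]))
      stop("bins must be sorted and non-overlapping on ", ch)
  }
  runs_for <- function(count, type) {
    qual <- count >= min_samples
    out <- NULL
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      r <- rle(qual[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in which(r$values)) {
        sel <- idx[starts[j]:ends[j]]
        out <- rbind(out, data.frame(
          chrom = ch, start = bins$start[sel[1]],
          end = bins$end[sel[length(sel)]], type = type,
          max_samples = max(count[sel]), stringsAsFactors = FALSE))
      }
    }
    out
  }
  res <- rbind(runs_for(colSums(calls == 1), "gain"),
               runs_for(colSums(calls == -1), "loss"))
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      max_samples = integer())
  rownames(res) <- NULL
  res
}

#' Breakpoint region around a copy-number transition point
#'
#' The window of fixed half-width (default 1 Mb, i.e. a 2 Mb region) around
#' a gain/loss transition point, clipped to the chromosome bounds.
#'
#' @param chrom chromosome of the transition point.
#' @param position transition point in bp (0-based).
#' @param half_width half-width of the window in bp (> 0).
#' @param chrom_lengths named chromosome lengths.
#' @return List `(chrom, start, end)` with `start < end`, half-open.
#' @export
define_breakpoint_region <- function(chrom, position, half_width = 1e6,
                                     chrom_lengths) {
  if (!chrom %in% names(chrom_lengths)) stop("unknown chromosome: ", chrom)
  len <- chrom_lengths[[chrom]]
  if (position < 0 || position >= len)
    stop("position ", position, " lies outside ", chrom)
  if (half_width <= 0) stop("half_width must be positive")
  list(chrom = chrom, start = max(0, position - half_width),
       end = min(len, position + half_width))
}

#' Permutation test of a cell-type expression difference in a region
#'
#' Tests whether the average difference between two smoothed expression
#' tracks (e.g. sympathoblast minus chromaffin) inside a genomic region is
#' larger than expected by chance. The observed statistic is the mean of
#' `track_a - track_b` over the region's grid points; the null is built
#' from `n_permutations` same-length windows placed uniformly at random
#' over all chromosomes long enough to hold the region. The p-value is the
#' plain fraction of null windows with a difference greater than or equal
#' to the observed one (optionally the (s+1)/(n+1) correction).
#'
#' @param track_a,track_b [smooth_expression_track()] tracks on the same
#'   grid and bandwidth.
#' @param region list `(chrom, start, end)` (half-open bp interval), e.g.
#'   from [define_breakpoint_region()].
#' @param n_permutations number of random windows (default 1000).
#' @param seed RNG seed (results are bit-reproducible for a fixed seed).
#' @param correct use the (s+1)/(n+1) estimator instead of the plain
#'   fraction (default `FALSE`).
#' @return List of class `region_test`: `region`, `observed_diff`,
#'   `null_diffs`, `p`, `n_permutations`.
#' @export
region_difference_test <- function(track_a, track_b, region,
                                   n_permutations = 1000, seed = 1,
                                   correct = FALSE) {
  stopifnot(is(track_a, "genomic_track"), is(track_b, "genomic_track"))
  if (!identical(track_a$pos, track_b$pos) ||
      !identical(track_a$chrom, track_b$chrom) ||
      !identical(attr(track_a, "bandwidth"), attr(track_b, "bandwidth")))
    stop("tracks must share grid and bandwidth")
  diff <- track_a$value - track_b$value
  chroms <- track_a$chrom
  in_region <- chroms == region$chrom & track_a$pos >= region$start &
    track_a$pos < region$end
  L <- sum(in_region)
  if (L == 0) stop("region contains no grid points")
  observed <- mean(diff[in_region])

  # windows of L consecutive grid points; O(1) means via cumulative sums
  chrom_names <- unique(chroms)
  windows <- lapply(chrom_names, function(ch) {
    v <- diff[chroms == ch]
    if (length(v) < L) return(numeric(0))
    cs <- c(0, cumsum(v))
    (cs[(L + 1):length(cs)] - cs[seq_len(length(cs) - L)]) / L
  })
  all_means <- unlist(windows)
  if (length(all_means) == 0)
    stop("region is longer than every chromosome")
  set.seed(seed)
  null_diffs <- all_means[sample.int(length(all_means), n_permutations,
                                     replace = TRUE)]
  s <- sum(null_diffs >= observed)
  p <- if (correct) (s + 1) / (n_permutations + 1) else s / n_permutations
  structure(list(region = region, observed_diff = observed,
                 null_diffs = null_diffs, p = p,
                 n_permutations = n_permutations),
            class = "region_test")
}

#' @export
print.region_test <- function(x, ...) {
  cat(sprintf("region_test: %s:%g-%g  observed diff %.4g  p = %.4g (%d permutations)\n",
              x$region$chrom, x$region$start, x$region$end,
              x$observed_diff, x$p, x$n_permutations))
  invisible(x)
}
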