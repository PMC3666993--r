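# Rank-cutoff peak-set concordance -----------------------------------------

#' Overlap fraction of two top-ranked peak lists
#'
#' Counts the peaks of the smaller list that overlap (by at least one base)
#' any peak of the other list, and divides by the size of the smaller list,
#' so the fraction is always in `[0, 1]` and each peak is counted once no
#' matter how many partners it overlaps.
#'
#' @param top_x,top_y `GRanges` rank-prefixes of two peak sets (see
#'   [top_peaks()]).
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(top_x, top_y) {
  if (length(top_x) == 0 || length(top_y) == 0)
    stop("overlap_fraction requires two non-empty peak lists")
  if (length(top_x) <= length(top_y)) {
    small <- top_x; big <- top_y
  } else {
    small <- top_y; big <- top_x
  }
  sum(overlapsAny(small, big, ignore.strand = TRUE)) / length(small)
}

#' Rank-cutoff overlap grid between two peak sets
#'
#' For every pair of rank cutoffs `(x, y)` on a grid of multiples of
#' `bin_width`, computes the fraction of the top-`x` peaks of `set1`
#' overlapping the top-`y` peaks of `set2`, normalized by the smaller
#' cutoff. For a fixed `x` the fraction is non-decreasing in `y`.
#'
#' @param set1,set2 `ranked_peaks` objects.
#' @param bin_width rank bin width (grid step).
#' @param max_rank largest cutoff; truncated with a warning when it exceeds
#'   the available peaks.
#' @return An object of class `"overlap_grid"`: list with the cutoff vector
#'   and the fraction matrix (`rows = set1` cutoffs, `cols = set2` cutoffs).
#' @export
overlap_grid <- function(set1, set2, bin_width = 5000L, max_rank = NULL) {
  n1 <- n_peaks(set1); n2 <- n_peaks(set2)
  if (n1 < bin_width || n2 < bin_width)
    stop("both peak sets must have at least `bin_width` peaks")
  avail <- min(n1, n2)
  if (is.null(max_rank)) max_rank <- avail
  if (max_rank > avail) {
    warning("max_rank ", max_rank, " exceeds available peaks; truncated to ",
            avail)
    max_rank <- avail
  }
  cutoffs <- seq.int(bin_width, max_rank, by = bin_width)
  if (max_rank %% bin_width != 0) cutoffs <- c(cutoffs, max_rank)
  frac <- matrix(NA_real_, length(cutoffs), length(cutoffs),
                 dimnames = list(cutoffs, cutoffs))
  # prefix overlap flags are monotone in the partner cutoff: compute the
  # minimal partner rank overlapping each peak once, then threshold
  p1 <- set1$peaks; p2 <- set2$peaks
  min_rank_in_2 <- first_partner_rank(p1, p2)
  min_rank_in_1 <- first_partner_rank(p2, p1)
  for (i in seq_along(cutoffs)) {
    x <- cutoffs[i]
    for (j in seq_along(cutoffs)) {
      y <- cutoffs[j]
      if (x <= y) {
        hits <- sum(min_rank_in_2[seq_len(x)] <= y)
      } else {
        hits <- sum(min_rank_in_1[seq_len(y)] <= x)
      }
      frac[i, j] <- hits / min(x, y)
    }
  }
  structure(list(cutoffs = cutoffs, fraction = frac,
                 samples = c(set1$sample, set2$sample)),
            class = "overlap_grid")
}

#' @keywords internal
first_partner_rank <- function(query, subject) {
  # for each query peak, the best (smallest) rank among overlapping subject
  # peaks; Inf when none overlaps
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  out <- rep(Inf, length(query))
  if (length(hits)) {
    r <- mcols(subject)$rank[subjectHits(hits)]
    agg <- tapply(r, queryHits(hits), min)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' @export
print.overlap_grid <- function(x, ...) {
  cat("<overlap_grid> samples: ", paste(x$samples, collapse = " vs "),
      "; cutoffs ", x$cutoffs[1], "..", x$cutoffs[length(x$cutoffs)],
      "\n", sep = "")
  print(round(x$fraction, 3))
  invisible(x)
}

#' @export
plot.overlap_grid <- function(x, ...) {
  n <- length(x$cutoffs)
  graphics::image(seq_len(n), seq_len(n), t(x$fraction[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = x$samples[2], ylab = x$samples[1],
                  zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(n), labels = x$cutoffs)
  graphics::axis(2, at = seq_len(n), labels = rev(x$cutoffs))
  invisible(x)
}

#' Pearson correlation of asinh-transformed peak heights
#'
#' The inverse hyperbolic sine behaves like a log for large heights but is
#' defined at zero, stabilizing variance before correlating matched-locus
#' peak heights of two samples.
#'
#' @param heights1,heights2 equal-length numeric vectors of matched-locus
#'   heights.
#' @return Pearson correlation in `[-1, 1]`, or `NA` when either vector has
#'   zero variance.
#' @export
asinh_pearson <- function(heights1, heights2) {
  stopifnot(length(heights1) == length(heights2))
  a <- asinh(heights1); b <- asinh(heights2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b, method = "pearson")
}

#' Matched-locus heights for two samples
#'
#' Takes the union of both peak sets' loci (merged where they overlap) and
#' reads the maximum depth at each locus from each sample's coverage, so a
#' locus missing from one sample's peak list still gets that sample's
#' actual local depth rather than zero.
#'
#' @param set1,set2 `ranked_peaks` objects.
#' @param cov1,cov2 the samples' [coverage_track]s (ideally built from
#'   read sets sub-sampled to equal size).
#' @return data.frame with the union loci and columns `height1`, `height2`.
#' @export
matched_heights <- function(set1, set2, cov1, cov2) {
  loci <- reduce(c(granges(set1$peaks), granges(set2$peaks)),
                 ignore.strand = TRUE)
  if (length(loci) == 0) stop("no loci to match")
  h1 <- max_depth_at(cov1, loci)
  h2 <- max_depth_at(cov2, loci)
  data.frame(chrom = as.character(seqnames(loci)),
             start = start(loci) - 1L, end = end(loci),
             height1 = h1, height2 = h2, stringsAsFactors = FALSE)
}

#' @keywords internal
max_depth_at <- function(coverage, loci) {
  out <- numeric(length(loci))
  for (chr in unique(as.character(seqnames(loci)))) {
    sel <- as.character(seqnames(loci)) == chr
    depth <- coverage$depth[[chr]]
    if (is.null(depth)) { out[sel] <- 0; next }
    s <- pmax(start(loci)[sel], 1L)
    e <- pmin(end(loci)[sel], length(depth))
    v <- Views(depth, start = s, end = e)
    out[sel] <- viewMaxs(v)
  }
  out
}

#' Distribution of peak-height ratios under equalized read counts
#'
#' Sub-samples both read sets to their common minimum, rebuilds coverage,
#' reads the height of every shared locus (peaks of `set1` overlapping
#' `set2`) in both samples, and summarizes `log2((h2 + 1) / (h1 + 1))`.
#'
#' @param set1,set2 `ranked_peaks` objects.
#' @param reads1,reads2 the samples' processed read `GRanges`.
#' @param genome the [genome].
#' @param extension read extension length.
#' @param probs quantiles to report.
#' @param seed sub-sampling seed.
#' @return List with `quantiles` (named numeric), `n_loci`, and the
#'   per-locus `table`.
#' @export
height_ratio_distribution <- function(set1, set2, reads1, reads2, genome,
                                      extension = 200L,
                                      probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                                      seed = 1L) {
  shared <- set1$peaks[overlapsAny(set1$peaks, set2$peaks,
                                   ignore.strand = TRUE)]
  if (length(shared) == 0) stop("no shared loci between the two peak sets")
  n <- min(length(reads1), length(reads2))
  r1 <- subsample_reads(reads1, n, seed = seed)
  r2 <- subsample_reads(reads2, n, seed = seed + 1L)
  c1 <- build_coverage(r1, genome, total_length = extension)
  c2 <- build_coverage(r2, genome, total_length = extension)
  h1 <- max_depth_at(c1, shared)
  h2 <- max_depth_at(c2, shared)
  lr <- log2((h2 + 1) / (h1 + 1))
  list(quantiles = quantile(lr, probs = probs, names = TRUE),
       n_loci = length(shared),
       n_reads_each = n,
       table = data.frame(chrom = as.character(seqnames(shared)),
                          start = start(shared) - 1L, end = end(shared),
                          height1 = h1, height2 = h2, log2_ratio = lr,
                          stringsAsFactors = FALSE))
}
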