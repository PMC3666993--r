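# Background model: negative binomial conditioned on GC ------------------

#' Truncation-corrected NB maximum likelihood
#'
#' Fits (mu, size) to counts observed conditional on `X <= ceiling`.
#' Underdispersed data collapse to the Poisson limit (`size = Inf`).
#' @keywords internal
fit_nb_truncated <- function(k, ceiling_d) {
  n <- length(k)
  if (n < 2) return(NULL)
  m <- mean(k)
  if (!is.finite(m) || m <= 0) return(NULL)
  v <- stats::var(k)
  if (v == 0) return(list(mu = m, size = Inf))
  tab <- table(k)
  vals <- as.integer(names(tab)); cnt <- as.numeric(tab)
  nll_nb <- function(par) {
    mu <- exp(par[1]); size <- exp(par[2])
    denom <- pnbinom(ceiling_d, size = size, mu = mu, log.p = TRUE)
    -(sum(cnt * dnbinom(vals, size = size, mu = mu, log = TRUE)) -
        n * denom)
  }
  nll_pois <- function(par) {
    mu <- exp(par[1])
    denom <- ppois(ceiling_d, lambda = mu, log.p = TRUE)
    -(sum(cnt * dpois(vals, lambda = mu, log = TRUE)) - n * denom)
  }
  size0 <- if (v > m) m^2 / (v - m) else 100
  opt <- stats::optim(c(log(m), log(size0)), nll_nb,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  mu_hat <- exp(opt$par[1]); size_hat <- exp(opt$par[2])
  if (size_hat > 1e4) {
    # effectively Poisson: refit the one-parameter truncated model
    optp <- stats::optimize(function(lm) nll_pois(lm),
                            interval = log(c(max(m / 10, 1e-8), m * 10)))
    return(list(mu = exp(optp$minimum), size = Inf))
  }
  list(mu = mu_hat, size = size_hat)
}

#' @keywords internal
window_table <- function(coverage, genome, window_size, gc_bin_width) {
  wins <- gc_windows(genome, window_size)
  map_ok <- window_map_fraction(genome, wins) >= 0.5
  gc <- mcols(wins)$gc
  usable <- map_ok & !is.na(gc)
  bins <- rep(NA_integer_, length(wins))
  bins[usable] <- gc_bin_index(gc[usable], gc_bin_width)
  counts <- NULL
  if (!is.null(coverage)) {
    anchors <- coverage$reads_extended
    counts <- unlist(lapply(seqlevels(wins), function(chr) {
      w <- wins[seqnames(wins) == chr]
      a <- start(anchors[seqnames(anchors) == chr])
      tab <- tabulate((a - 1L) %/% window_size + 1L, nbins = length(w))
      tab
    }))
  }
  list(windows = wins, bins = bins, usable = usable, counts = counts)
}

#' Fit the GC-conditioned negative-binomial background model
#'
#' The genome is tiled into non-overlapping windows (one extension length
#' wide by default, so that per-base read depth and windowed counts of
#' extended-read anchors share a scale); each window is assigned a GC bin
#' (N bases excluded, windows mostly non-mappable dropped); and per-bin
#' negative-binomial parameters are estimated per bin by
#' truncation-corrected maximum likelihood under signal masking: windows
#' above a robust ceiling (median plus three lower-half interquartile
#' ranges, so bound windows in the upper tail cannot move it) are masked,
#' and the NB likelihood is maximized conditional on counts not exceeding
#' the ceiling — the conditioning makes the fit unbiased on pure
#' background no matter how aggressive the ceiling is. The ceiling is then
#' tightened to the `mask_alpha` upper tail of the fit where that is
#' lower, and the fit repeated (`max_rounds` rounds).
#' Underdispersed bins (variance <= mean) fall back to a Poisson law
#' (`size = Inf`). Bins with fewer than `min_windows` usable windows inherit
#' the nearest fitted bin's parameters.
#'
#' @param coverage a [coverage_track] from [build_coverage()].
#' @param genome the [genome] the coverage was built on.
#' @param window_size window width (default: the coverage's extension).
#' @param gc_bin_width width of GC-fraction bins.
#' @param mask_alpha upper-tail probability used to mask signal windows.
#' @param max_rounds masking/refitting rounds.
#' @param min_windows minimum usable windows for a bin to be fitted.
#' @return An object of class `"nbgc_model"` with per-bin `mu`, `size`
#'   (`Inf` marks the Poisson fallback), `fitted` flag and window counts.
#' @export
fit_background <- function(coverage, genome,
                           window_size = coverage$extension,
                           gc_bin_width = 0.05,
                           mask_alpha = 1e-4,
                           max_rounds = 5L,
                           min_windows = 200L) {
  wt <- window_table(coverage, genome, window_size, gc_bin_width)
  n_bins <- ceiling(1 / gc_bin_width)
  mu <- rep(NA_real_, n_bins); size <- rep(NA_real_, n_bins)
  fitted <- rep(FALSE, n_bins); n_win <- integer(n_bins)
  if (!any(wt$usable)) stop("no usable windows in any GC bin")
  for (b in seq_len(n_bins)) {
    idx <- which(wt$usable & wt$bins == b)
    n_win[b] <- length(idx)
    if (length(idx) < min_windows) next
    k <- wt$counts[idx]
    # robust ceiling: the spread estimate uses only the lower half of the
    # count distribution, so signal windows (upper tail) cannot move it
    qs <- as.numeric(stats::quantile(k, c(0.25, 0.5), type = 1))
    ceiling_d <- qs[2] + 3 * max(2 * (qs[2] - qs[1]), 1)
    fit <- NULL
    for (round in seq_len(max_rounds)) {
      fit <- fit_nb_truncated(k[k <= ceiling_d], ceiling_d)
      if (is.null(fit)) break
      tighter <- if (is.finite(fit$size))
        qnbinom(mask_alpha, size = fit$size, mu = fit$mu,
                lower.tail = FALSE)
      else qpois(mask_alpha, lambda = fit$mu, lower.tail = FALSE)
      if (tighter >= ceiling_d) break
      ceiling_d <- tighter
    }
    if (is.null(fit) || !is.finite(fit$mu) || fit$mu <= 0) next
    mu[b] <- fit$mu
    size[b] <- fit$size
    fitted[b] <- TRUE
  }
  if (!any(fitted)) stop("no GC bin had enough windows to fit")
  # unfitted bins inherit nearest fitted bin
  fit_idx <- which(fitted)
  for (b in which(!fitted)) {
    nb <- fit_idx[which.min(abs(fit_idx - b))]
    mu[b] <- mu[nb]; size[b] <- size[nb]
  }
  structure(list(gc_bin_width = gc_bin_width,
                 gc_bin_edges = seq(0, by = gc_bin_width,
                                    length.out = n_bins + 1L),
                 mu = mu, size = size, fitted = fitted,
                 n_windows = n_win,
                 window_size = as.integer(window_size),
                 total_reads = coverage$total_reads),
            class = "nbgc_model")
}

#' @export
print.nbgc_model <- function(x, ...) {
  cat("<nbgc_model> window ", x$window_size, " bp, GC bins of ",
      x$gc_bin_width, "; ", sum(x$fitted), " bin(s) fitted from ",
      x$total_reads, " reads\n", sep = "")
  invisible(x)
}

#' @export
summary.nbgc_model <- function(object, ...) {
  n_bins <- length(object$mu)
  df <- data.frame(
    gc_lo = object$gc_bin_edges[seq_len(n_bins)],
    gc_hi = object$gc_bin_edges[-1],
    n_windows = object$n_windows,
    mu = object$mu,
    size = object$size,
    fitted = object$fitted
  )
  df[df$n_windows > 0 | df$fitted, , drop = FALSE]
}

#' @keywords internal
model_params_at <- function(model, gc) {
  if (any(gc < 0 | gc > 1, na.rm = TRUE))
    stop("gc must lie in [0, 1]")
  b <- gc_bin_index(gc, model$gc_bin_width)
  list(mu = model$mu[b], size = model$size[b])
}

#' Negative-binomial tail probability of an observed count
#'
#' Returns `P(X >= observed)` under the NB law of the GC bin containing
#' `gc`; bins fitted as Poisson (`size = Inf`) use the Poisson tail.
#' Monotone non-increasing in `observed`.
#'
#' @param model an [fit_background()] model.
#' @param gc GC fraction(s) in `[0, 1]`.
#' @param observed observed count(s), non-negative.
#' @return Numeric vector of tail probabilities in `(0, 1]`.
#' @export
nb_tail_pvalue <- function(model, gc, observed) {
  p <- model_params_at(model, gc)
  n <- max(length(gc), length(observed))
  mu <- rep_len(p$mu, n); size <- rep_len(p$size, n)
  obs <- rep_len(observed, n)
  out <- numeric(n)
  pois <- is.infinite(size)
  if (any(pois))
    out[pois] <- ppois(obs[pois] - 1, lambda = mu[pois], lower.tail = FALSE)
  if (any(!pois))
    out[!pois] <- pnbinom(obs[!pois] - 1, size = size[!pois],
                          mu = mu[!pois], lower.tail = FALSE)
  out[obs <= 0] <- 1
  out
}

#' @keywords internal
depth_threshold <- function(model, bins, p) {
  # smallest integer d with P(X >= d) <= p, per GC bin index
  mu <- model$mu[bins]; size <- model$size[bins]
  d <- ifelse(is.infinite(size),
              qpois(p, lambda = mu, lower.tail = FALSE) + 1,
              qnbinom(p, size = size, mu = mu, lower.tail = FALSE) + 1)
  pmax(d, 1)
}

# Peak calling ------------------------------------------------------------

#' @keywords internal
new_ranked_peaks <- function(gr, sample, total_reads, p_threshold) {
  structure(list(peaks = gr, sample = sample, total_reads = total_reads,
                 p_threshold = p_threshold),
            class = "ranked_peaks")
}

#' @export
print.ranked_peaks <- function(x, ...) {
  cat("<ranked_peaks> ", length(x$peaks), " peak(s)",
      if (!is.na(x$sample)) paste0(" [", x$sample, "]"),
      ", p threshold ", format(x$p_threshold), "\n", sep = "")
  if (length(x$peaks)) {
    cat("  top peaks:\n")
    print(utils::head(x$peaks, 3))
  }
  invisible(x)
}

#' Number of peaks in a ranked peak set
#' @param x a `ranked_peaks` object.
#' @return Integer count.
#' @export
n_peaks <- function(x) length(x$peaks)

#' Top-ranked prefix of a peak set
#' @param x a `ranked_peaks` object.
#' @param n prefix size (clipped to the available peaks).
#' @return `GRanges` of the `n` best-ranked peaks.
#' @export
top_peaks <- function(x, n) {
  x$peaks[seq_len(min(n, length(x$peaks)))]
}

#' Call peaks against the GC-conditioned background
#'
#' Candidate regions are maximal runs of bases whose depth meets the per-GC
#' depth threshold implied by `p_threshold`; runs closer than
#' `merge_distance` bases are merged. Each region is reported with its
#' summit (position of maximum depth), height (that maximum) and the NB
#' tail p-value of the height in the summit's GC bin, then ranked by
#' ascending p-value with ties broken by descending height and coordinate.
#'
#' @param coverage a [coverage_track].
#' @param model an `nbgc_model` fitted from the same sample.
#' @param genome the [genome].
#' @param p_threshold p-value cutoff.
#' @param merge_distance merge runs separated by fewer than this many bases.
#' @param sample optional sample label carried in the result.
#' @return A `ranked_peaks` object.
#' @export
call_peaks <- function(coverage, model, genome, p_threshold = 1e-10,
                       merge_distance = 200L, sample = NA_character_) {
  wt <- window_table(NULL, genome, model$window_size, model$gc_bin_width)
  wins <- wt$windows
  chroms <- seqlevels(wins)
  all_gr <- list()
  for (chr in chroms) {
    in_chr <- as.character(seqnames(wins)) == chr
    bins <- wt$bins[in_chr]
    thr_val <- rep(Inf, sum(in_chr))
    has_bin <- !is.na(bins)
    thr_val[has_bin] <- depth_threshold(model, bins[has_bin], p_threshold)
    thr <- Rle(thr_val, width(wins)[in_chr])
    depth <- coverage$depth[[chr]]
    if (is.null(depth) || length(depth) == 0) next
    ok <- depth >= thr
    ir <- methods::as(ok, "IRanges")
    if (length(ir) == 0) next
    ir <- reduce(ir, min.gapwidth = merge_distance)
    v <- Views(depth, ir)
    height <- viewMaxs(v)
    summit <- viewWhichMaxs(v)
    win_of_summit <- (summit - 1L) %/% model$window_size + 1L
    gc_bin <- bins[win_of_summit]
    pv <- rep(NA_real_, length(ir))
    hb <- !is.na(gc_bin)
    if (any(hb)) {
      mu <- model$mu[gc_bin[hb]]; size <- model$size[gc_bin[hb]]
      pv[hb] <- ifelse(is.infinite(size),
                       ppois(height[hb] - 1, mu, lower.tail = FALSE),
                       pnbinom(height[hb] - 1, size = size, mu = mu,
                               lower.tail = FALSE))
    }
    gr <- GRanges(chr, ir, seqinfo = genome_seqinfo(genome))
    mcols(gr)$height <- height
    mcols(gr)$summit <- summit
    mcols(gr)$p_value <- pv
    all_gr[[chr]] <- gr
  }
  if (length(all_gr) == 0) {
    pk <- GRanges()
    mcols(pk)$height <- numeric(0); mcols(pk)$summit <- integer(0)
    mcols(pk)$p_value <- numeric(0); mcols(pk)$rank <- integer(0)
    return(new_ranked_peaks(pk, sample, coverage$total_reads, p_threshold))
  }
  gr <- do.call(c, unname(all_gr))
  gr <- gr[!is.na(mcols(gr)$p_value)]
  o <- order(mcols(gr)$p_value, -mcols(gr)$height,
             as.integer(match(as.character(seqnames(gr)), chroms)),
             start(gr))
  gr <- gr[o]
  mcols(gr)$rank <- seq_along(gr)
  new_ranked_peaks(gr, sample, coverage$total_reads, p_threshold)
}

#' Remove peaks overlapping control peaks
#'
#' Control peaks are called from pooled control reads at a lenient
#' threshold; sample peaks overlapping any control peak by at least one
#' base are removed as likely artifacts and the remaining peaks re-ranked.
#'
#' @param peaks a `ranked_peaks` object.
#' @param control_peaks a `ranked_peaks` object (or `GRanges`) of control
#'   peaks.
#' @return A `ranked_peaks` object with ranks `1..N` recomputed.
#' @export
subtract_control <- function(peaks, control_peaks) {
  ctrl <- if (inherits(control_peaks, "ranked_peaks")) control_peaks$peaks
  else control_peaks
  gr <- peaks$peaks
  if (length(ctrl) && length(gr)) {
    drop <- overlapsAny(gr, ctrl, ignore.strand = TRUE)
    gr <- gr[!drop]
  }
  if (length(gr)) mcols(gr)$rank <- seq_along(gr)
  new_ranked_peaks(gr, peaks$sample, peaks$total_reads, peaks$p_threshold)
}

# Empirical FDR curve ------------------------------------------------------

#' Empirical FDR curve from observed vs model-expected genome coverage
#'
#' For each p-value cutoff, computes the fraction of (usable) genome bases
#' whose depth reaches the per-GC depth threshold (`observed_fraction`), the
#' model-expected fraction (`null_fraction`, the attainable NB tail mass at
#' the discrete threshold averaged over GC bins), and their ratio
#' `fdr = null_fraction / observed_fraction`, capped at 1. Cutoffs with no
#' observed coverage report `NA` (undefined).
#'
#' @param coverage a [coverage_track].
#' @param model an `nbgc_model`.
#' @param genome the [genome].
#' @param p_grid vector of p-value cutoffs.
#' @return A data.frame of class `"fdr_curve"` with columns `p`,
#'   `observed_fraction`, `null_fraction`, `fdr`.
#' @export
fdr_curve <- function(coverage, model, genome, p_grid = 10^-(3:8)) {
  wt <- window_table(NULL, genome, model$window_size, model$gc_bin_width)
  wins <- wt$windows
  chroms <- seqlevels(wins)
  usable_bases <- sum(as.numeric(width(wins)[wt$usable]))
  bin_w <- tapply(as.numeric(width(wins)[wt$usable]),
                  wt$bins[wt$usable], sum)
  bin_idx <- as.integer(names(bin_w))
  out <- data.frame(p = p_grid, observed_fraction = NA_real_,
                    null_fraction = NA_real_, fdr = NA_real_)
  for (j in seq_along(p_grid)) {
    p <- p_grid[j]
    d <- depth_threshold(model, bin_idx, p)
    mu <- model$mu[bin_idx]; size <- model$size[bin_idx]
    tail_mass <- ifelse(is.infinite(size),
                        ppois(d - 1, mu, lower.tail = FALSE),
                        pnbinom(d - 1, size = size, mu = mu,
                                lower.tail = FALSE))
    null_frac <- sum(bin_w * tail_mass) / usable_bases
    covered <- 0
    for (chr in chroms) {
      in_chr <- as.character(seqnames(wins)) == chr
      bins <- wt$bins[in_chr]
      thr_val <- rep(Inf, sum(in_chr))
      hb <- !is.na(bins)
      thr_val[hb] <- depth_threshold(model, bins[hb], p)
      thr <- Rle(thr_val, width(wins)[in_chr])
      depth <- coverage$depth[[chr]]
      if (is.null(depth) || length(depth) == 0) next
      covered <- covered + sum(runLength(depth >= thr)[
        runValue(depth >= thr)])
    }
    obs_frac <- covered / usable_bases
    out$observed_fraction[j] <- obs_frac
    out$null_fraction[j] <- null_frac
    out$fdr[j] <- if (obs_frac > 0) min(null_frac / obs_frac, 1) else NA_real_
  }
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' @export
plot.fdr_curve <- function(x, ...) {
  graphics::plot(-log10(x$p), log10(pmax(x$observed_fraction, 1e-12)),
                 type = "b", pch = 19,
                 xlab = "-log10 p-value cutoff",
                 ylab = "log10 genome fraction covered", ...)
  graphics::lines(-log10(x$p), log10(pmax(x$null_fraction, 1e-12)),
                  type = "b", col = "red", pch = 1)
  graphics::legend("topright", legend = c("observed", "model"),
                   col = c("black", "red"), pch = c(19, 1), lty = 1)
  invisible(x)
}
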