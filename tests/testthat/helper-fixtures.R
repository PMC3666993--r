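# Shared fixtures, built once per session and memoized. The "standard"
# fixture is the full two-sample design at its default scale (3 x 2 Mb,
# 5,000 shared sites, dose factor 4); the "small" fixture is a 1/10-scale
# version used by module-level tests.

.fixture_env <- new.env(parent = emptyenv())

small_synthetic_config <- function(seed = 7L, ...) {
  args <- list(n_chroms = 2L, chrom_length = 300000L,
               n_true_sites = 500L, n_fg_reads = 35000L,
               n_repeat_tracts = 4L, n_tss = 50L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

small_fixture <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- small_synthetic_config()
  sim <- simulate_genome(cfg)
  samples <- c(endogenous = "endogenous", overexpressed = "overexpressed",
               control = "control")
  reads <- lapply(samples, function(s)
    simulate_reads(sim$genome, sim$truth, cfg, s))
  proc <- lapply(reads, deduplicate_reads)
  cov <- lapply(proc, function(r)
    build_coverage(r, sim$genome, total_length = cfg$fragment_length))
  models <- lapply(cov, function(x) fit_background(x, sim$genome))
  ctrl <- call_peaks(cov$control, models$control, sim$genome,
                     p_threshold = 1e-3, sample = "control")
  peaks <- lapply(c("endogenous", "overexpressed"), function(s)
    subtract_control(call_peaks(cov[[s]], models[[s]], sim$genome,
                                p_threshold = 1e-10, sample = s), ctrl))
  names(peaks) <- c("endogenous", "overexpressed")
  .fixture_env$small <- list(cfg = cfg, genome = sim$genome,
                             truth = sim$truth, reads = reads, proc = proc,
                             cov = cov, models = models,
                             control_peaks = ctrl, peaks = peaks)
  .fixture_env$small
}

std_fixture <- function() {
  if (!is.null(.fixture_env$std)) return(.fixture_env$std)
  cfg <- synthetic_config(seed = 42L)
  sim <- simulate_genome(cfg)
  samples <- c(endogenous = "endogenous", overexpressed = "overexpressed",
               control = "control")
  reads <- lapply(samples, function(s)
    simulate_reads(sim$genome, sim$truth, cfg, s))
  proc <- lapply(reads, deduplicate_reads)
  cov <- lapply(proc, function(r)
    build_coverage(r, sim$genome, total_length = cfg$fragment_length))
  models <- lapply(cov, function(x) fit_background(x, sim$genome))
  ctrl <- call_peaks(cov$control, models$control, sim$genome,
                     p_threshold = 1e-3, sample = "control")
  peaks <- lapply(c("endogenous", "overexpressed"), function(s)
    subtract_control(call_peaks(cov[[s]], models[[s]], sim$genome,
                                p_threshold = 1e-10, sample = s), ctrl))
  names(peaks) <- c("endogenous", "overexpressed")
  .fixture_env$std <- list(cfg = cfg, genome = sim$genome,
                           truth = sim$truth, reads = reads, proc = proc,
                           cov = cov, models = models,
                           control_peaks = ctrl, peaks = peaks)
  .fixture_env$std
}

# A single-bin NB model with prescribed parameters (for tail-probability
# oracles that need no fitting).
manual_nb_model <- function(mu, size, window_size = 200L) {
  structure(list(gc_bin_width = 1, gc_bin_edges = c(0, 1),
                 mu = mu, size = size, fitted = TRUE,
                 n_windows = 1L, window_size = as.integer(window_size),
                 total_reads = NA_integer_),
            class = "nbgc_model")
}

# Independent oracle: NB upper-tail mass by direct summation of the
# probability mass function out to a far truncation point.
nb_tail_brute <- function(mu, size, observed, truncate = 50000L) {
  if (observed <= 0) return(1)
  xs <- observed:truncate
  if (is.infinite(size)) sum(dpois(xs, lambda = mu))
  else sum(dnbinom(xs, size = size, mu = mu))
}

random_genome <- function(seed, lengths = c(chr1 = 5000L, chr2 = 4000L),
                          gc = 0.5) {
  set.seed(seed)
  seqs <- vapply(lengths, function(n)
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
           collapse = ""), character(1))
  genome(seqs)
}

random_seq <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# Planted-PWM experiment used by motif-recovery checks: each foreground
# window carries one occurrence drawn from an RRCAGSTG-consensus PWM.
planted_pwm_matrix <- function() {
  cols <- list(R1 = c(.5, 0, .5, 0), R2 = c(.5, 0, .5, 0),
               C = c(0, 1, 0, 0), A = c(1, 0, 0, 0), G = c(0, 0, 1, 0),
               S = c(0, .5, .5, 0), T = c(0, 0, 0, 1), G2 = c(0, 0, 1, 0))
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

planted_motif_sets <- function(n_fg = 500L, n_bg = 500L, width = 101L,
                               seed = 11L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pm <- planted_pwm_matrix()
  w <- ncol(pm)
  fg <- vapply(seq_len(n_fg), function(i) {
    occ <- paste0(vapply(seq_len(w), function(j)
      sample(bases, 1, prob = pm[, j]), character(1)), collapse = "")
    s <- random_seq(width)
    pos <- sample.int(width - w + 1L, 1)
    paste0(substr(s, 1, pos - 1L), occ, substr(s, pos + w, width))
  }, character(1))
  bg <- vapply(seq_len(n_bg), function(i) random_seq(width), character(1))
  list(fg = peakdose:::new_sequence_set(fg, "foreground"),
       bg = peakdose:::new_sequence_set(bg, "background"),
       pwm = pm)
}

# strand-aware mean per-column total-variation distance between two PWMs
pwm_tv_distance <- function(prob, ref) {
  flip <- prob[4:1, ncol(prob):1, drop = FALSE]
  min(mean(colSums(abs(prob - ref)) / 2),
      mean(colSums(abs(flip - ref)) / 2))
}

# IUPAC-compatibility: does `word` contain a stretch whose letter sets
# intersect `core`'s at every position (either strand)?
word_contains_core <- function(word, core) {
  sets <- peakdose:::IUPAC_SETS
  check_one <- function(wrd) {
    wl <- strsplit(wrd, "")[[1]]; cl <- strsplit(core, "")[[1]]
    k <- length(cl)
    if (length(wl) < k) return(FALSE)
    for (off in 0:(length(wl) - k)) {
      ok <- all(vapply(seq_len(k), function(i)
        length(intersect(sets[[wl[off + i]]], sets[[cl[i]]])) > 0,
        logical(1)))
      if (ok) return(TRUE)
    }
    FALSE
  }
  check_one(word) ||
    check_one(peakdose:::revcomp_chr(word))
}
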