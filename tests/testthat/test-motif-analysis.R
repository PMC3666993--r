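seqset <- function(x, role = "foreground") {
  peakdose:::new_sequence_set(x, role)
}

test_that("PWM construction validates its invariants", {
  p <- matrix(0.25, 4, 6)
  pwm <- new_pwm(p)
  expect_equal(pwm$width, 6)
  expect_error(new_pwm(matrix(c(0.5, 0.5, 0.1, 0.1), 4, 2)), "sum to 1")
  bad <- p; bad[1, 1] <- 0; bad[2, 1] <- 0.5
  expect_error(new_pwm(bad), "positive")
})

test_that("two-proportion z matches the hand formula on a 20+20 toy", {
  hit_f <- 12L; hit_b <- 5L; n_f <- 20L; n_b <- 20L
  pf <- hit_f / n_f; pb <- hit_b / n_b; p <- (hit_f + hit_b) / (n_f + n_b)
  hand <- (pf - pb) / sqrt(p * (1 - p) * (1 / n_f + 1 / n_b))
  expect_equal(peakdose:::two_prop_z(hit_f, n_f, hit_b, n_b), hand)
  expect_equal(peakdose:::two_prop_z(0L, 20L, 0L, 20L), 0)
})

test_that("constructed 80/10 planting yields the expected statistics", {
  set.seed(14)
  mk <- function(n, with_motif) vapply(seq_len(n), function(i) {
    s <- random_seq(60)
    if (with_motif)
      s <- paste0(substr(s, 1, 20), "CAGCTG", substr(s, 27, 60))
    s
  }, character(1))
  # make sure the background occurrences are exact: plant in 10% of bg
  fg <- c(mk(80, TRUE), mk(20, FALSE))
  bg <- c(mk(10, TRUE), mk(90, FALSE))
  # random sequence can contain chance CAGCTG hits; count what is planted
  fgs <- seqset(fg); bgs <- seqset(bg, "background")
  res <- discover_motifs(fgs, bgs, k = 6L, n_motifs = 1L, min_z = 3)
  expect_length(res, 1)
  expect_true(word_contains_core(res[[1]]$consensus, "CAGCTG"))
  exp_fg <- mean(peakdose:::matches_degenerate(fg, res[[1]]$consensus))
  exp_bg <- mean(peakdose:::matches_degenerate(bg, res[[1]]$consensus))
  expect_equal(res[[1]]$fg_frac, exp_fg)
  expect_equal(res[[1]]$bg_frac, exp_bg)
  expect_equal(res[[1]]$ratio, exp_fg / exp_bg)
  expect_gt(res[[1]]$fg_frac, 0.7)
  expect_lt(res[[1]]$bg_frac, 0.3)
})

test_that("identical foreground and background yields no motif", {
  set.seed(15)
  s <- vapply(1:60, function(i) random_seq(80), character(1))
  res <- discover_motifs(seqset(s), seqset(s, "background"), k = 6L,
                         n_motifs = 3L)
  expect_length(res, 0)
})

test_that("EM refinement recovers an exactly planted word", {
  set.seed(16)
  fg <- vapply(1:120, function(i) {
    s <- random_seq(60)
    pos <- sample.int(55, 1)
    paste0(substr(s, 1, pos - 1), "CAGCTG", substr(s, pos + 6, 60))
  }, character(1))
  pwm <- em_refine("CAGCTG", seqset(fg))
  idx <- cbind(match(strsplit("CAGCTG", "")[[1]], c("A", "C", "G", "T")),
               1:6)
  direct <- all(pwm$prob[idx] >= 0.9)
  flipped <- pwm$prob[4:1, 6:1]
  expect_true(direct || all(flipped[idx] >= 0.9))
  expect_true(all(diff(pwm$em$objective) >= -1e-8))
  expect_true(all(abs(colSums(pwm$prob) - 1) < 1e-9))
})

test_that("EM objective is non-decreasing on heterogeneous inputs", {
  set.seed(17)
  for (rep in 1:3) {
    fg <- vapply(1:40, function(i) random_seq(50), character(1))
    pwm <- em_refine("CANNTG", seqset(fg), max_iter = 40L)
    expect_true(all(diff(pwm$em$objective) >= -1e-8))
    expect_true(all(abs(colSums(pwm$prob) - 1) < 1e-9))
  }
})

test_that("a seed with no match mass returns the flagged seed PWM", {
  fg <- seqset(c("AAAAAAAAAA", "AAAAAAAAAA"))
  pwm <- em_refine("CCGGCC", fg)
  expect_true(pwm$em$degenerate)
  expect_false(pwm$em$converged)
  expect_equal(pwm$width, 6)
})

test_that("PWM scoring honours log-odds identities and strand symmetry", {
  bgf <- rep(0.25, 4)
  flat <- new_pwm(matrix(0.25, 4, 6), background = bgf)
  expect_equal(pwm_score(flat, random_seq(30)), 0)
  # near-delta PWM on CAGCTG: best score equals the hand computation
  pc <- 0.25
  counts <- matrix(0, 4, 6)
  idx <- cbind(match(strsplit("CAGCTG", "")[[1]], c("A", "C", "G", "T")),
               1:6)
  counts[idx] <- 1
  prob <- sweep(counts + pc / 4, 2, colSums(counts + pc / 4), "/")
  delta <- new_pwm(prob, background = bgf)
  hand <- 6 * log2((1 + pc / 4) / (1 + pc) / 0.25)
  expect_equal(pwm_score(delta, "TTCAGCTGTT"), hand, tolerance = 1e-12)
  # reverse-complemented window scores identically
  set.seed(18)
  for (i in 1:10) {
    w <- random_seq(25)
    p <- matrix(stats::runif(24) + 0.05, 4, 6)
    p <- sweep(p, 2, colSums(p), "/")
    pwm <- new_pwm(p, background = bgf)
    expect_equal(pwm_score(pwm, w),
                 pwm_score(pwm, peakdose:::revcomp_chr(w)),
                 tolerance = 1e-12)
  }
  # non-ACGT bases invalidate placements; all-invalid gives NA
  expect_true(is.na(pwm_score(delta, "NNNNNN")))
})

test_that("background sampling matches GC and TSS-distance structure", {
  fx <- small_fixture()
  fg <- make_foreground(fx$peaks$endogenous, fx$genome, flank = 50L,
                        max_peaks = 60L)
  bg <- sample_background(fx$genome, fg, n_per_fg = 1L, gc_tol = 0.02,
                          seed = 9L)
  expect_length(bg$seqs, length(fg$seqs))
  gc_of <- function(s) {
    f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(s),
                                     c("C", "G"))
    rowSums(f) / nchar(s)
  }
  expect_lt(abs(mean(gc_of(bg$seqs)) - mean(gc_of(fg$seqs))), 0.02)
  expect_false(any(IRanges::overlapsAny(bg$windows, fg$windows)))
  # TSS-distance bin histogram matches exactly (tally oracle)
  tss <- fx$genome$tss
  dist_bin <- function(w) {
    d <- GenomicRanges::distance(
      w, tss[GenomicRanges::nearest(w, tss, ignore.strand = TRUE)],
      ignore.strand = TRUE)
    d
  }
  d_fg <- log10(dist_bin(fg$windows) + 1)
  d_bg <- log10(dist_bin(bg$windows) + 1)
  breaks <- seq(0, max(d_fg) + 1e-9, length.out = 11L)
  expect_equal(table(findInterval(d_bg, breaks, all.inside = TRUE)),
               table(findInterval(d_fg, breaks, all.inside = TRUE)))
})

test_that("average PWM score by rank bin matches brute recomputation", {
  fx <- small_fixture()
  pk <- fx$peaks$endogenous
  pwm <- peakdose:::seed_pwm("RRCAGSTG")
  bw <- 40L
  tab <- avg_pwm_by_rank(pk, pwm, fx$genome, bin_width = bw,
                         floor_score = -20)
  gr <- pk$peaks
  # brute recomputation for the first bin
  sel <- which(gr$rank <= bw)
  scores <- vapply(sel, function(i) {
    chr <- as.character(seqnames(gr))[i]
    s <- peakdose:::extract_seqs(fx$genome, gr[i])
    hits <- Biostrings::matchPattern("CANNTG", Biostrings::DNAString(s),
                                     fixed = FALSE)
    ok <- grepl("^CA[ACGT][ACGT]TG$", as.character(hits))
    if (!any(ok)) return(-20)
    best <- -Inf
    for (p in start(hits)[ok]) {
      a <- max(1L, start(gr)[i] + p - 1L - 4L)
      b <- min(chrom_lengths(fx$genome)[[chr]], start(gr)[i] + p - 1L + 9L)
      win <- peakdose:::extract_seqs(
        fx$genome, GenomicRanges::GRanges(chr, IRanges::IRanges(a, b)))
      sc <- pwm_score(pwm, win)
      if (!is.na(sc)) best <- max(best, sc)
    }
    if (is.finite(best)) best else -20
  }, numeric(1))
  expect_equal(tab$mean_score[1], mean(scores), tolerance = 1e-9)
  expect_equal(tab$n[1], length(sel))
})

test_that("motif tables expose the sign convention and round-trip", {
  res <- list(
    structure(list(consensus = "CAGCTG", pwm = NULL, z_score = 8.1,
                   ratio = 2.0, fg_frac = 0.5, bg_frac = 0.25),
              class = "motif_result"),
    structure(list(consensus = "AATTAA", pwm = NULL, z_score = -3.3,
                   ratio = 0.5, fg_frac = 0.2, bg_frac = 0.4),
              class = "motif_result"))
  tab <- motif_table(res)
  expect_equal(tab$ratio[1], tab$fg_frac[1] / tab$bg_frac[1])
  expect_lt(tab$z_score[tab$fg_frac < tab$bg_frac], 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  peakdose:::write_tsv(tab, f)
  back <- peakdose:::read_tsv(f)
  expect_equal(back$consensus, tab$consensus)
  expect_equal(back$z_score, tab$z_score)
  # empty result set gives an empty table
  expect_equal(nrow(motif_table(list())), 0)
})

test_that("MEME output lists one record per PWM", {
  pwm <- peakdose:::seed_pwm("CAGCTG")
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(a = pwm, b = pwm), f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^MOTIF", lines)), 2)
  expect_true(any(grepl("letter-probability matrix", lines)))
})
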