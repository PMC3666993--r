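test_that("NB tail probabilities match brute-force mass summation", {
  for (mu in c(0.5, 2, 5, 20)) {
    for (size in c(0.5, 2, 10, Inf)) {
      model <- manual_nb_model(mu, size)
      for (obs in c(0, 1, 3, 10, 60)) {
        got <- nb_tail_pvalue(model, 0.5, obs)
        want <- nb_tail_brute(mu, size, obs)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
  # observed = 0 is total mass
  expect_equal(nb_tail_pvalue(manual_nb_model(5, 5), 0.5, 0), 1)
  # Poisson fallback agrees with the closed-form Poisson tail
  expect_equal(nb_tail_pvalue(manual_nb_model(5, Inf), 0.5, 15),
               ppois(14, 5, lower.tail = FALSE), tolerance = 1e-12)
  # monotone non-increasing in the observed count
  pv <- nb_tail_pvalue(manual_nb_model(5, 5), 0.5, 0:100)
  expect_true(all(diff(pv) <= 0))
  expect_error(nb_tail_pvalue(manual_nb_model(5, 5), 1.2, 3), "gc")
})

test_that("mu=5, var=10 (size 5) tail at 20 matches direct summation", {
  model <- manual_nb_model(5, 5)  # var = mu + mu^2/size = 10
  expect_equal(nb_tail_pvalue(model, 0.5, 20),
               nb_tail_brute(5, 5, 20), tolerance = 1e-10)
})

test_that("background fit recovers known NB parameters per GC bin", {
  cfg <- synthetic_config(n_chroms = 1L, chrom_length = 2e6, n_true_sites = 0L,
                          bg_mu_intercept = 8, bg_mu_slope = 24, bg_size = 5,
                          n_repeat_tracts = 0L, seed = 31L)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg, "endogenous")
  cov <- build_coverage(reads, sim$genome, 200L)
  mod <- fit_background(cov, sim$genome)
  s <- summary(mod)
  big <- s[s$n_windows >= 1000 & s$fitted, ]
  expect_gt(nrow(big), 0)
  mids <- (big$gc_lo + big$gc_hi) / 2
  truth_mu <- 8 + 24 * mids
  expect_true(all(abs(big$mu - truth_mu) / truth_mu < 0.05))
  expect_true(all(abs(big$size - 5) / 5 < 0.3))
})

test_that("constant coverage collapses to the Poisson fallback", {
  g <- genome(c(chr1 = random_seq(100000)))
  # one + read anchored at the start of every 200-base window: every
  # window count is exactly 1
  st <- seq(1, 100000 - 199, by = 200)
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = 36),
                              strand = "+")
  cov <- build_coverage(r, g, 200L)
  mod <- fit_background(cov, g, min_windows = 50L)
  expect_equal(sum(summary(mod)$n_windows), 500L)
  s <- summary(mod)
  expect_true(all(is.infinite(s$size[s$fitted])))
  expect_true(all(abs(s$mu[s$fitted] - 1) < 1e-9))
})

test_that("GC-independent background fits equal means across bins", {
  cfg <- synthetic_config(n_chroms = 1L, chrom_length = 2e6,
                          n_true_sites = 0L, bg_mu_intercept = 10,
                          bg_mu_slope = 0, bg_size = 5,
                          n_repeat_tracts = 0L, seed = 13L)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim$genome, sim$truth, cfg, "endogenous")
  cov <- build_coverage(reads, sim$genome, 200L)
  mod <- fit_background(cov, sim$genome)
  s <- summary(mod)
  big <- s[s$fitted & s$n_windows >= 500, ]
  # sampling error accounts for the gamma-rate block correlation
  # (bg_block / window_size windows share a rate draw)
  win_per_block <- cfg$bg_block / cfg$window_size
  se <- sqrt(10 / big$n_windows +
               (10^2 / cfg$bg_size) / (big$n_windows / win_per_block))
  expect_gt(nrow(big), 1)
  expect_true(all(abs(big$mu - 10) < 3 * se))
})

test_that("isolated read stacks become single peaks with correct summits", {
  g <- genome(c(chr1 = random_seq(50000)))
  # background: one anchor per window keeps the model finite
  st_bg <- seq(1, 50000 - 199, by = 200)
  bg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st_bg, width = 36),
                               strand = "+")
  stack <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(rep(10001L, 30),
                                                   width = 36),
                                  strand = "+")
  cov <- build_coverage(c(bg, stack), g, 200L)
  mod <- manual_nb_model(1, Inf)
  pk <- call_peaks(cov, mod, g, p_threshold = 1e-10, sample = "t")
  expect_equal(n_peaks(pk), 1)
  expect_equal(pk$peaks$height[1], 31)
  expect_true(pk$peaks$summit[1] >= 10001 && pk$peaks$summit[1] <= 10200)
  expect_equal(pk$peaks$p_value[1],
               ppois(30, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("nearby candidate runs merge within one fragment length", {
  g <- genome(c(chr1 = random_seq(50000)))
  mk_stack <- function(pos) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rep(pos, 30L), width = 36), strand = "+")
  mod <- manual_nb_model(1, Inf)
  # gap of 150 between extended stacks -> merged
  close_pair <- c(mk_stack(10001L), mk_stack(10351L))
  pk <- call_peaks(build_coverage(close_pair, g, 200L), mod, g, 1e-10)
  expect_equal(n_peaks(pk), 1)
  # gap of 400 -> two peaks
  far_pair <- c(mk_stack(10001L), mk_stack(10601L))
  pk2 <- call_peaks(build_coverage(far_pair, g, 200L), mod, g, 1e-10)
  expect_equal(n_peaks(pk2), 2)
})

test_that("peak ranks are a deterministic permutation sorted by evidence", {
  fx <- small_fixture()
  pk <- fx$peaks$endogenous
  expect_setequal(pk$peaks$rank, seq_len(n_peaks(pk)))
  p <- pk$peaks$p_value
  h <- pk$peaks$height
  expect_true(all(diff(p) >= 0))
  ties <- which(diff(p) == 0)
  expect_true(all(h[ties + 1] <= h[ties]))
})

test_that("control subtraction removes overlapping peaks and re-ranks", {
  mk <- function(starts, heights) {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(starts, width = 100))
    S4Vectors::mcols(gr)$height <- heights
    S4Vectors::mcols(gr)$summit <- starts + 50L
    S4Vectors::mcols(gr)$p_value <- 10^-(heights)
    gr <- gr[order(S4Vectors::mcols(gr)$p_value)]
    S4Vectors::mcols(gr)$rank <- seq_along(gr)
    peakdose:::new_ranked_peaks(gr, "s", 1000L, 1e-3)
  }
  pk <- mk(seq(1, 10000, by = 1000), heights = 10:1)
  ctrl <- mk(c(1001, 3001, 9001), heights = c(3, 3, 3))
  out <- subtract_control(pk, ctrl)
  expect_equal(n_peaks(out), 7)
  expect_equal(out$peaks$rank, 1:7)
  expect_false(any(IRanges::overlapsAny(out$peaks, ctrl$peaks)))
  # peak strictly inside a control peak is removed
  inside <- mk(1021, 5)
  expect_equal(n_peaks(subtract_control(inside, ctrl)), 0)
  # empty control set is the identity
  empty <- peakdose:::new_ranked_peaks(GenomicRanges::GRanges(), "c",
                                       0L, 1e-3)
  expect_equal(n_peaks(subtract_control(pk, empty)), 10)
})

test_that("null fraction of the FDR curve equals analytic bin-mass sums", {
  fx <- small_fixture()
  mod <- fx$models$endogenous
  fc <- fdr_curve(fx$cov$endogenous, mod, fx$genome, p_grid = c(1e-3, 1e-5))
  wt <- peakdose:::window_table(NULL, fx$genome, mod$window_size,
                                mod$gc_bin_width)
  w <- tapply(as.numeric(width(wt$windows)[wt$usable]),
              wt$bins[wt$usable], sum)
  bins <- as.integer(names(w))
  for (j in seq_along(fc$p)) {
    d <- peakdose:::depth_threshold(mod, bins, fc$p[j])
    tails <- ifelse(is.infinite(mod$size[bins]),
                    ppois(d - 1, mod$mu[bins], lower.tail = FALSE),
                    pnbinom(d - 1, size = mod$size[bins], mu = mod$mu[bins],
                            lower.tail = FALSE))
    expect_equal(fc$null_fraction[j], sum(w * tails) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("planted signal drives the FDR far below one at stringent cutoffs", {
  fx <- small_fixture()
  fc <- fdr_curve(fx$cov$endogenous, fx$models$endogenous, fx$genome,
                  p_grid = 10^-(3:8))
  expect_lt(fc$fdr[fc$p == 1e-8], 0.1)
  # fdr is capped at 1 and NA only where nothing is observed
  expect_true(all(is.na(fc$fdr) | fc$fdr <= 1))
  expect_true(all(fc$observed_fraction[is.na(fc$fdr)] == 0))
})
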