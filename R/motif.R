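# Position weight matrices ------------------------------------------------

#' Construct a position weight matrix
#'
#' @param prob 4 x w matrix of per-position base probabilities (rows A,C,G,T;
#'   each column must sum to 1 within 1e-9, all entries > 0).
#' @param background length-4 base frequencies used for log-odds scoring.
#' @param pseudocount pseudocount used during estimation (metadata).
#' @param consensus optional consensus string (metadata).
#' @return An object of class `"pwm"`.
#' @export
new_pwm <- function(prob, background = rep(0.25, 4), pseudocount = NA_real_,
                    consensus = NA_character_) {
  prob <- as.matrix(prob)
  stopifnot(nrow(prob) == 4, ncol(prob) >= 1)
  if (any(abs(colSums(prob) - 1) > 1e-9))
    stop("PWM columns must each sum to 1")
  if (any(prob <= 0))
    stop("PWM entries must be positive (apply a pseudocount)")
  rownames(prob) <- c("A", "C", "G", "T")
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  structure(list(prob = prob, width = ncol(prob),
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T")),
                 pseudocount = pseudocount, consensus = consensus),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width ", x$width,
      if (!is.na(x$consensus)) paste0(", consensus ", x$consensus),
      "\n", sep = "")
  print(round(x$prob, 3))
  invisible(x)
}

#' Write PWMs in MEME minimal text format
#'
#' @param pwms list of [new_pwm()] objects (named, or names taken from
#'   consensus strings).
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  nms <- names(pwms)
  if (is.null(nms))
    nms <- vapply(seq_along(pwms), function(i) {
      cs <- pwms[[i]]$consensus
      if (is.na(cs)) paste0("motif_", i) else cs
    }, character(1))
  bg <- pwms[[1]]$background
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    writeLines(c(sprintf("MOTIF %s", nms[i]),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         p$width)), con)
    writeLines(apply(t(p$prob), 1, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(NULL)
}

# IUPAC helpers ------------------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"),
                   S = c("C", "G"), W = c("A", "T"),
                   N = c("A", "C", "G", "T"))

#' @keywords internal
iupac_consensus_letter <- function(p, threshold = 0.6) {
  # smallest IUPAC set (within the scoring alphabet) covering the dominant
  # probability mass of a PWM column
  bases <- c("A", "C", "G", "T")
  o <- order(p, decreasing = TRUE)
  if (p[o[1]] >= threshold) return(bases[o[1]])
  pair <- sort(bases[o[1:2]])
  for (code in c("R", "Y", "S", "W"))
    if (identical(sort(IUPAC_SETS[[code]]), pair)) return(code)
  "N"
}

#' @keywords internal
pwm_consensus <- function(prob) {
  paste0(vapply(seq_len(ncol(prob)), function(j)
    iupac_consensus_letter(prob[, j]), character(1)), collapse = "")
}

#' @keywords internal
word_compatible <- function(word, pattern) {
  # every letter of `word` drawn from the corresponding IUPAC set of
  # `pattern` (same length)
  if (nchar(word) != nchar(pattern)) return(FALSE)
  w <- strsplit(word, "")[[1]]; p <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(w), function(i) {
    sw <- IUPAC_SETS[[w[i]]]; sp <- IUPAC_SETS[[p[i]]]
    !is.null(sw) && !is.null(sp) && all(sw %in% sp)
  }, logical(1)))
}

# Sequence sets -------------------------------------------------------------

#' @keywords internal
new_sequence_set <- function(seqs, role, windows = NULL) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0) stop("empty sequence set")
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("all windows must have the same width")
  structure(list(role = role, seqs = seqs, width = w, windows = windows),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", length(x$seqs), " ", x$role,
      " window(s) of width ", x$width, "\n", sep = "")
  invisible(x)
}

#' @keywords internal
extract_seqs <- function(genome, gr) {
  out <- character(length(gr))
  chr_all <- as.character(seqnames(gr))
  for (chr in unique(chr_all)) {
    sel <- chr_all == chr
    subject <- genome$seq[[match(chr, names(genome$seq))]]
    v <- Views(subject, start = start(gr)[sel], end = end(gr)[sel])
    out[sel] <- as.character(v)
  }
  out
}

#' Foreground sequence windows around peak summits
#'
#' @param peaks a `ranked_peaks` object (or `GRanges` with a `summit`
#'   column).
#' @param genome the [genome].
#' @param flank half-width; windows are `2 * flank + 1` wide, centered on
#'   summits. Windows running past a chromosome end are dropped.
#' @param max_peaks optional cap on the number of (top-ranked) peaks used.
#' @return A foreground `"sequence_set"`.
#' @export
make_foreground <- function(peaks, genome, flank = 50L, max_peaks = NULL) {
  gr <- if (inherits(peaks, "ranked_peaks")) peaks$peaks else peaks
  if (!is.null(max_peaks)) gr <- utils::head(gr, max_peaks)
  if (length(gr) == 0) stop("no peaks")
  summit <- mcols(gr)$summit
  if (is.null(summit)) summit <- (start(gr) + end(gr)) %/% 2L
  lens <- chrom_lengths(genome)
  st <- summit - flank; en <- summit + flank
  ok <- st >= 1L & en <= lens[as.character(seqnames(gr))]
  win <- GRanges(seqnames(gr)[ok], IRanges(start = st[ok], end = en[ok]))
  new_sequence_set(extract_seqs(genome, win), "foreground", windows = win)
}

#' Sample GC- and TSS-distance-matched background windows
#'
#' For each foreground window, draws `n_per_fg` random genomic windows with
#' GC within `gc_tol` of the foreground window's GC and the same log-scaled
#' distance-to-TSS bin, never overlapping a foreground window. When a
#' window's quota cannot be filled after bounded retries, the GC tolerance
#' is progressively relaxed (and finally the TSS constraint dropped) with a
#' warning. Deterministic given `seed`.
#'
#' @param genome a [genome] with TSS annotations (windows fall back to a
#'   single TSS bin when `tss` is absent).
#' @param fg foreground `"sequence_set"` from [make_foreground()].
#' @param n_per_fg background windows per foreground window.
#' @param gc_tol GC-fraction matching tolerance.
#' @param tss_bins number of log10 distance-to-TSS bins.
#' @param seed sampling seed.
#' @return A background `"sequence_set"`.
#' @export
sample_background <- function(genome, fg, n_per_fg = 1L, gc_tol = 0.02,
                              tss_bins = 10L, seed = 1L) {
  stopifnot(inherits(fg, "sequence_set"), !is.null(fg$windows))
  set.seed(as.integer(seed))
  width <- fg$width
  lens <- chrom_lengths(genome)
  chroms <- names(lens)

  gc_of <- function(seqs) {
    freq <- letterFrequency(DNAStringSet(seqs), c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    ifelse(acgt == 0, NA_real_, (freq[, "C"] + freq[, "G"]) / acgt)
  }
  tss_bin_of <- function(gr, breaks) {
    if (is.null(genome$tss) || length(genome$tss) == 0)
      return(rep(1L, length(gr)))
    d <- GenomicRanges::distance(gr, genome$tss[
      GenomicRanges::nearest(gr, genome$tss, ignore.strand = TRUE)],
      ignore.strand = TRUE)
    d[is.na(d)] <- max(lens)
    findInterval(log10(d + 1), breaks, all.inside = TRUE)
  }

  fg_gc <- gc_of(fg$seqs)
  if (is.null(genome$tss) || length(genome$tss) == 0) {
    breaks <- c(0, Inf)
  } else {
    d_fg <- GenomicRanges::distance(fg$windows, genome$tss[
      GenomicRanges::nearest(fg$windows, genome$tss,
                             ignore.strand = TRUE)], ignore.strand = TRUE)
    d_fg[is.na(d_fg)] <- max(lens)
    breaks <- seq(0, max(log10(d_fg + 1)) + 1e-9,
                  length.out = tss_bins + 1L)
  }
  fg_bin <- tss_bin_of(fg$windows, breaks)

  n_fg <- length(fg$seqs)
  need <- rep(seq_len(n_fg), each = n_per_fg)
  got_gr <- vector("list", length(need))
  got_seq <- character(length(need))
  unmet <- seq_along(need)
  tol <- gc_tol
  use_bin <- TRUE
  rounds <- 0L
  while (length(unmet) > 0) {
    rounds <- rounds + 1L
    if (rounds > 40L) {
      if (tol < 0.2) {
        tol <- tol * 2
        warning("relaxing background GC tolerance to ", tol, " for ",
                length(unmet), " unmet window(s)")
      } else if (use_bin) {
        use_bin <- FALSE
        warning("dropping TSS-distance matching for ", length(unmet),
                " unmet window(s)")
      }
      rounds <- 0L
    }
    n_cand <- max(2000L, 20L * length(unmet))
    c_chr <- sample(chroms, n_cand, replace = TRUE,
                    prob = lens / sum(lens))
    c_start <- floor(runif(n_cand, 1, lens[c_chr] - width + 1))
    cand <- GRanges(c_chr, IRanges(start = c_start, width = width))
    cand <- cand[!overlapsAny(cand, fg$windows, ignore.strand = TRUE)]
    if (length(cand) == 0) next
    c_seq <- extract_seqs(genome, cand)
    c_gc <- gc_of(c_seq)
    keep <- !is.na(c_gc)
    cand <- cand[keep]; c_seq <- c_seq[keep]; c_gc <- c_gc[keep]
    if (length(cand) == 0) next
    c_bin <- tss_bin_of(cand, breaks)
    used <- rep(FALSE, length(cand))
    still <- integer(0)
    for (u in unmet) {
      i <- need[u]
      ok <- !used & abs(c_gc - fg_gc[i]) <= tol &
        (!use_bin | c_bin == fg_bin[i])
      j <- which(ok)[1]
      if (is.na(j)) { still <- c(still, u); next }
      used[j] <- TRUE
      got_gr[[u]] <- cand[j]
      got_seq[u] <- c_seq[j]
    }
    unmet <- still
  }
  win <- unname(do.call(c, got_gr))
  new_sequence_set(got_seq, "background", windows = win)
}

# Discriminative discovery ---------------------------------------------------

#' @keywords internal
two_prop_z <- function(hit_f, n_f, hit_b, n_b) {
  pf <- hit_f / n_f; pb <- hit_b / n_b
  p <- (hit_f + hit_b) / (n_f + n_b)
  den <- sqrt(p * (1 - p) * (1 / n_f + 1 / n_b))
  ifelse(den == 0, 0, (pf - pb) / den)
}

#' @keywords internal
presence_exact_kmers <- function(seqs, k) {
  # per-sequence presence (either strand) of every exact k-mer; returns a
  # named count vector over the 4^k words (windows containing N are ignored,
  # which makes previously masked matches invisible)
  freq <- oligonucleotideFrequency(DNAStringSet(seqs), width = k)
  pres <- freq > 0L
  words <- colnames(freq)
  rc_map <- match(revcomp_chr(words), words)
  either <- pres | pres[, rc_map, drop = FALSE]
  stats::setNames(colSums(either), words)
}

#' @keywords internal
presence_degenerate <- function(seqs, word) {
  sum(matches_degenerate(seqs, word))
}

#' @keywords internal
presence_degenerate_codes <- function(C, word) {
  # number of sequences (rows of the code matrix) containing the IUPAC word
  # on either strand; code 0 (N/masked) never matches
  letters_w <- strsplit(toupper(word), "")[[1]]
  w <- length(letters_w)
  L <- ncol(C); n <- nrow(C)
  if (w > L) return(0L)
  m <- L - w + 1L
  bases <- c("A", "C", "G", "T")
  hit_f <- matrix(TRUE, n, m)
  hit_r <- matrix(TRUE, n, m)
  for (t in seq_len(w)) {
    set <- IUPAC_SETS[[letters_w[t]]]
    if (is.null(set)) stop("not an IUPAC letter: ", letters_w[t])
    allow <- c(FALSE, bases %in% set)           # index by code + 1
    allow_rc <- c(FALSE, rev(bases %in% set))   # complement: code 5 - b
    hit_f <- hit_f & matrix(allow[C[, t:(t + m - 1L), drop = FALSE] + 1L],
                            n, m)
    cols <- (w - t + 1L):(w - t + m)
    hit_r <- hit_r & matrix(allow_rc[C[, cols, drop = FALSE] + 1L], n, m)
  }
  sum(rowSums(hit_f) + rowSums(hit_r) > 0)
}

#' @keywords internal
mask_word <- function(seqs, word) {
  # replace matches of `word` (either strand) with N runs
  pat <- DNAString(word)
  subj <- DNAStringSet(seqs)
  for (p in list(pat, reverseComplement(pat))) {
    m <- vmatchPattern(p, subj, fixed = FALSE)
    for (i in seq_along(seqs)) {
      r <- m[[i]]
      if (length(r) == 0) next
      for (j in seq_along(r))
        substr(seqs[i], start(r)[j], end(r)[j]) <-
          paste0(rep("N", width(r)[j]), collapse = "")
    }
  }
  seqs
}

#' Discriminative de novo motif discovery
#'
#' Enumerates all exact words of length `k` and scores each by a
#' two-proportion z-statistic comparing the fraction of foreground versus
#' background sequences containing the word on either strand. The top word
#' is greedily generalized one position at a time over the degenerate
#' alphabet `{A,C,G,T,R,Y,S,W,N}` while the |z| improves, refined into a
#' PWM by ZOOPS EM on the foreground ([em_refine()]), its matches masked,
#' and the search repeated for up to `n_motifs` motifs. Positive z marks
#' enrichment in the foreground, negative z depletion.
#'
#' @param fg,bg `"sequence_set"` objects (foreground and background).
#' @param k word length (must not exceed the window width).
#' @param n_motifs maximum motifs to report.
#' @param min_z stop when no remaining word reaches this |z|.
#' @param refine run EM refinement (disable for speed in word-level scans).
#' @param pseudocount per-base pseudocount for PWM estimation.
#' @return List of `"motif_result"` objects: `consensus`, `pwm`, `z_score`,
#'   `ratio`, `fg_frac`, `bg_frac`.
#' @export
discover_motifs <- function(fg, bg, k = 6L, n_motifs = 5L, min_z = 3,
                            refine = TRUE, pseudocount = 0.25) {
  stopifnot(inherits(fg, "sequence_set"), inherits(bg, "sequence_set"))
  if (k > fg$width || k > bg$width)
    stop("word length k exceeds the window width")
  fgs <- fg$seqs; bgs <- bg$seqs
  n_f <- length(fgs); n_b <- length(bgs)
  results <- list()
  for (iter in seq_len(n_motifs)) {
    cf <- presence_exact_kmers(fgs, k)
    cb <- presence_exact_kmers(bgs, k)
    z <- two_prop_z(cf, n_f, cb, n_b)
    best <- which.max(abs(z))
    if (length(best) == 0 || abs(z[best]) < min_z) break
    word <- names(cf)[best]
    best_z <- z[best]
    Cf <- encode_seqs(fgs); Cb <- encode_seqs(bgs)
    # greedy single-position degeneration while |z| improves
    repeat {
      letters_w <- strsplit(word, "")[[1]]
      improved <- FALSE
      for (pos in seq_len(k)) {
        cur_set <- IUPAC_SETS[[letters_w[pos]]]
        for (code in c("R", "Y", "S", "W", "N")) {
          if (!all(cur_set %in% IUPAC_SETS[[code]]) ||
              length(IUPAC_SETS[[code]]) <= length(cur_set)) next
          cand <- letters_w; cand[pos] <- code
          cand_word <- paste0(cand, collapse = "")
          zc <- two_prop_z(presence_degenerate_codes(Cf, cand_word), n_f,
                           presence_degenerate_codes(Cb, cand_word), n_b)
          if (abs(zc) > abs(best_z) + 1e-9) {
            word <- cand_word; best_z <- zc; improved <- TRUE
            letters_w <- cand
          }
        }
      }
      if (!improved) break
    }
    hit_f <- presence_degenerate_codes(Cf, word)
    hit_b <- presence_degenerate_codes(Cb, word)
    fg_frac <- hit_f / n_f; bg_frac <- hit_b / n_b
    pwm <- if (refine && hit_f > 0)
      em_refine(word, new_sequence_set(fgs, "foreground"),
                pseudocount = pseudocount)
    else seed_pwm(word, pseudocount = pseudocount)
    res <- structure(list(consensus = word, pwm = pwm,
                          z_score = unname(best_z),
                          ratio = if (bg_frac > 0) fg_frac / bg_frac else Inf,
                          fg_frac = fg_frac, bg_frac = bg_frac),
                     class = "motif_result")
    results[[length(results) + 1L]] <- res
    fgs <- mask_word(fgs, word)
    bgs <- mask_word(bgs, word)
  }
  results
}

#' @export
print.motif_result <- function(x, ...) {
  cat("<motif_result> ", x$consensus, ": z = ", round(x$z_score, 2),
      ", ratio = ", round(x$ratio, 2),
      ", fg ", round(x$fg_frac, 3), " vs bg ", round(x$bg_frac, 3),
      "\n", sep = "")
  invisible(x)
}

#' Tabulate motif discovery results
#'
#' One row per motif: consensus, discriminative z (positive = enriched,
#' negative = depleted), fg/bg enrichment ratio, and the fractions of
#' foreground and background sequences containing the motif.
#'
#' @param results list of `"motif_result"` from [discover_motifs()].
#' @return data.frame with columns `consensus`, `z_score`, `ratio`,
#'   `fg_frac`, `bg_frac`.
#' @export
motif_table <- function(results) {
  if (length(results) == 0)
    return(data.frame(consensus = character(0), z_score = numeric(0),
                      ratio = numeric(0), fg_frac = numeric(0),
                      bg_frac = numeric(0)))
  data.frame(
    consensus = vapply(results, `[[`, character(1), "consensus"),
    z_score = vapply(results, `[[`, numeric(1), "z_score"),
    ratio = vapply(results, `[[`, numeric(1), "ratio"),
    fg_frac = vapply(results, `[[`, numeric(1), "fg_frac"),
    bg_frac = vapply(results, `[[`, numeric(1), "bg_frac"),
    stringsAsFactors = FALSE)
}

# EM refinement --------------------------------------------------------------

#' @keywords internal
seed_pwm <- function(word, match_mass = 0.85, pseudocount = 0.25,
                     background = rep(0.25, 4)) {
  letters_w <- strsplit(toupper(word), "")[[1]]
  prob <- vapply(letters_w, function(l) {
    set <- IUPAC_SETS[[l]]
    if (is.null(set)) stop("not an IUPAC letter: ", l)
    p <- rep((1 - match_mass) / (4 - length(set)), 4)
    if (length(set) == 4) p <- rep(0.25, 4)
    else p[match(set, c("A", "C", "G", "T"))] <- match_mass / length(set)
    p
  }, numeric(4))
  new_pwm(prob, background = background, pseudocount = pseudocount,
          consensus = toupper(word))
}

#' @keywords internal
encode_seqs <- function(seqs) {
  # n x L integer matrix of base codes A=1 C=2 G=3 T=4, 0 otherwise
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  codes <- matrix(0L, length(seqs), L)
  lookup <- integer(128)
  lookup[utf8ToInt("A")] <- 1L; lookup[utf8ToInt("C")] <- 2L
  lookup[utf8ToInt("G")] <- 3L; lookup[utf8ToInt("T")] <- 4L
  for (i in seq_along(seqs))
    codes[i, ] <- lookup[utf8ToInt(seqs[i])]
  codes
}

#' ZOOPS expectation-maximization refinement of a seed word into a PWM
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) mixture: each
#' sequence either contains no motif occurrence or exactly one at some
#' offset on either strand. The E-step computes the posterior over
#' (no occurrence, every offset x strand) under the current PWM and a
#' 0-order background; the M-step re-estimates PWM columns with a Dirichlet
#' pseudocount and the occurrence prior. The EM objective (log-likelihood
#' plus the Dirichlet log-prior) is non-decreasing at every iteration and
#' is recorded, together with the raw data log-likelihood, in the returned
#' PWM's `em` field.
#'
#' @param seed_word IUPAC word used to initialize the PWM.
#' @param fg foreground `"sequence_set"`.
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the largest PWM entry change.
#' @param pseudocount Dirichlet pseudocount per base per column.
#' @param background length-4 background base frequencies (default:
#'   estimated from the foreground set).
#' @return A `"pwm"` whose `em` field holds `objective`, `loglik`,
#'   `lambda`, `iterations`, `converged`; when the seed has no match mass
#'   at all the seed-derived PWM is returned with `converged = FALSE` and
#'   `degenerate = TRUE`.
#' @export
em_refine <- function(seed_word, fg, max_iter = 100L, tol = 1e-4,
                      pseudocount = 0.25, background = NULL) {
  stopifnot(inherits(fg, "sequence_set"))
  w <- nchar(seed_word)
  L <- fg$width
  if (w > L) stop("seed word longer than the windows")
  C <- encode_seqs(fg$seqs)
  n <- nrow(C); m <- L - w + 1L
  if (is.null(background)) {
    tab <- tabulate(C[C > 0], nbins = 4)
    background <- (tab + 1) / (sum(tab) + 4)
  }
  if (presence_degenerate_codes(C, seed_word) == 0L) {
    # zero seed occurrences: return the seed-derived PWM, flagged
    out <- seed_pwm(seed_word, pseudocount = pseudocount,
                    background = background)
    out$em <- list(objective = numeric(0), loglik = numeric(0),
                   lambda = NA_real_, iterations = 0L, converged = FALSE,
                   degenerate = TRUE, seed = toupper(seed_word))
    return(out)
  }
  lb <- log(background)
  lbvec <- c(-Inf, lb)
  # per-window 0-order background log-probability (fixed across iterations)
  B <- matrix(0, n, m)
  for (t in seq_len(w))
    B <- B + matrix(lbvec[C[, t:(t + m - 1L), drop = FALSE] + 1L], n, m)

  pwm0 <- seed_pwm(seed_word, pseudocount = pseudocount,
                   background = background)
  theta <- pwm0$prob
  lambda <- 0.5
  objective <- numeric(0)
  loglik <- numeric(0)
  converged <- FALSE
  degenerate <- FALSE
  iter_done <- 0L

  for (iter in seq_len(max_iter)) {
    lt <- log(theta)
    Sf <- matrix(0, n, m); Sr <- matrix(0, n, m)
    for (t in seq_len(w)) {
      vf <- c(-Inf, lt[, t])
      Sf <- Sf + matrix(vf[C[, t:(t + m - 1L), drop = FALSE] + 1L], n, m)
      vr <- c(-Inf, rev(lt[, t]))
      cols <- (w - t + 1L):(w - t + m)
      Sr <- Sr + matrix(vr[C[, cols, drop = FALSE] + 1L], n, m)
    }
    Rf <- exp(Sf - B); Rr <- exp(Sr - B)
    Rf[!is.finite(Rf)] <- 0; Rr[!is.finite(Rr)] <- 0
    Rsum <- rowSums(Rf) + rowSums(Rr)
    if (iter == 1L && all(Rsum == 0)) {
      degenerate <- TRUE
      break
    }
    D <- (1 - lambda) + lambda / (2 * m) * Rsum
    ll <- sum(log(D))
    obj <- ll + pseudocount * sum(log(theta))
    loglik <- c(loglik, ll)
    objective <- c(objective, obj)
    Wf <- (lambda / (2 * m)) * Rf / D
    Wr <- (lambda / (2 * m)) * Rr / D
    # M-step
    counts <- matrix(0, 4, w)
    for (t in seq_len(w)) {
      codes_f <- C[, t:(t + m - 1L), drop = FALSE]
      codes_r <- C[, (w - t + 1L):(w - t + m), drop = FALSE]
      for (b in 1:4) {
        counts[b, t] <- counts[b, t] + sum(Wf[codes_f == b]) +
          sum(Wr[codes_r == (5L - b)])
      }
    }
    theta_new <- sweep(counts + pseudocount, 2,
                       colSums(counts + pseudocount), "/")
    lambda <- mean(rowSums(Wf) + rowSums(Wr))
    lambda <- min(max(lambda, 1e-6), 1 - 1e-6)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    iter_done <- iter
    if (delta < tol) { converged <- TRUE; break }
  }

  out <- new_pwm(theta, background = background, pseudocount = pseudocount,
                 consensus = pwm_consensus(theta))
  out$em <- list(objective = objective, loglik = loglik, lambda = lambda,
                 iterations = iter_done, converged = converged,
                 degenerate = degenerate, seed = toupper(seed_word))
  out
}

# PWM scoring ----------------------------------------------------------------

#' Best log-odds PWM score of a window
#'
#' Scores every placement of the PWM on both strands of the window as the
#' sum of `log2(p_base / bg_base)` and returns the maximum. Placements
#' containing a non-ACGT base are skipped; if every placement is skipped
#' the score is `NA`.
#'
#' @param pwm a `"pwm"`.
#' @param window character string (length >= PWM width).
#' @return Numeric best score (or `NA`).
#' @export
pwm_score <- function(pwm, window) {
  scores <- pwm_score_many(pwm, window)
  scores[1]
}

#' Best PWM scores of many windows
#'
#' Vectorized form of [pwm_score()]; windows may differ in length.
#'
#' @param pwm a `"pwm"`.
#' @param windows character vector of sequences.
#' @return Numeric vector of best scores (`NA` where undefined).
#' @export
pwm_score_many <- function(pwm, windows) {
  w <- pwm$width
  lodds <- log2(pwm$prob / pwm$background)
  vapply(windows, function(s) {
    L <- nchar(s)
    if (L < w) return(NA_real_)
    codes <- encode_seqs(s)[1, ]
    m <- L - w + 1L
    best <- -Inf
    for (j in seq_len(m)) {
      cs <- codes[j:(j + w - 1L)]
      if (all(cs > 0)) {
        sf <- sum(lodds[cbind(cs, seq_len(w))])
        sr <- sum(lodds[cbind(5L - rev(cs), seq_len(w))])
        best <- max(best, sf, sr)
      }
    }
    if (is.finite(best)) best else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Average best E-box PWM score by peak rank bin
#'
#' For each peak, finds the E-boxes (CANNTG) inside the peak interval,
#' scores a window around each with the PWM (best placement, both strands),
#' and takes the maximum; peaks containing no E-box contribute
#' `floor_score`. Scores are averaged within rank bins.
#'
#' @param peaks a `ranked_peaks` object.
#' @param pwm a `"pwm"`.
#' @param genome the [genome].
#' @param bin_width rank bin width.
#' @param floor_score score assigned to peaks without an E-box.
#' @return data.frame with columns `bin`, `rank_lo`, `rank_hi`, `n`,
#'   `mean_score`.
#' @export
avg_pwm_by_rank <- function(peaks, pwm, genome, bin_width = 5000L,
                            floor_score = -20) {
  gr <- peaks$peaks
  if (length(gr) == 0) stop("no peaks")
  pad <- (pwm$width - 6L) + 2L
  lens <- chrom_lengths(genome)
  per_peak <- vapply(seq_along(gr), function(i) {
    chr <- as.character(seqnames(gr))[i]
    s <- start(gr)[i]; e <- end(gr)[i]
    subject <- genome$seq[[match(chr, names(genome$seq))]]
    seq_pk <- as.character(subseq(subject, s, e))
    hits <- matchPattern("CANNTG", DNAString(seq_pk), fixed = FALSE)
    ok <- grepl("^CA[ACGT][ACGT]TG$", as.character(hits))
    if (!any(ok)) return(floor_score)
    st_abs <- s + start(hits)[ok] - 1L
    wins <- vapply(st_abs, function(p) {
      a <- max(1L, p - pad); b <- min(lens[[chr]], p + 5L + pad)
      as.character(subseq(subject, a, b))
    }, character(1))
    sc <- pwm_score_many(pwm, wins)
    if (all(is.na(sc))) floor_score else max(sc, na.rm = TRUE)
  }, numeric(1))
  rank <- mcols(gr)$rank
  bin <- (rank - 1L) %/% bin_width + 1L
  agg_mean <- tapply(per_peak, bin, mean)
  agg_n <- tapply(per_peak, bin, length)
  b <- as.integer(names(agg_mean))
  data.frame(bin = b,
             rank_lo = (b - 1L) * bin_width + 1L,
             rank_hi = pmin(b * bin_width, max(rank)),
             n = as.integer(agg_n),
             mean_score = as.numeric(agg_mean))
}
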