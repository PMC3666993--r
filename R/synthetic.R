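#' Synthetic-data configuration
#'
#' Parameters of the synthetic genome / binding-site / read generator. The
#' defaults describe the standard desk-scale two-sample design: a
#' 3 x 2 Mb genome with three GC levels, 5,000 shared true binding sites
#' with log-normal graded affinities coupled to chromatin accessibility, an
#' "overexpressed" sample carrying four-fold the foreground read mass of the
#' "endogenous" sample, and a GC-dependent negative-binomial background.
#'
#' Background reads are generated as a Gamma-Poisson process: each 200-base
#' window's expected read count is `bg_mu_intercept + bg_mu_slope * gc` (GC
#' taken at the mid-point of the window's GC bin), and a Gamma multiplier of
#' shape `bg_size` is shared across each `bg_block`-base block, so windowed
#' counts are marginally negative binomial with mean mu and size `bg_size`
#' while per-base depth keeps the same marginal law.
#'
#' Planted E-boxes favour the GC/CC internal dinucleotides (cores CAGCTG and
#' CAGGTG, the latter reverse-complement-equivalent to CACCTG), with the
#' probability of a preferred core and of consensus `RR`/`S` flanking bases
#' increasing with the site's effective-affinity quantile. CAGCTG E-boxes
#' carry a latent log-normal accessibility score thresholded at 1 and 2 into
#' low / moderate / high classes that multiply site occupancy.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bases).
#' @param gc_levels GC fractions of the three equal segments of each
#'   chromosome (recycled across chromosomes).
#' @param n_true_sites number of true binding sites.
#' @param affinity_sdlog sdlog of the log-normal per-site affinity weights
#'   (0 = equal affinities).
#' @param dose_factor multiplier on foreground read mass for the
#'   overexpressed sample.
#' @param n_fg_reads foreground reads in the endogenous sample.
#' @param bg_mu_intercept,bg_mu_slope background NB mean per window as a
#'   linear function of GC-bin midpoint.
#' @param bg_size background NB size (dispersion) parameter.
#' @param bg_block length (bases) over which the background Gamma rate
#'   multiplier persists.
#' @param window_size background window width; matches the read extension.
#' @param gc_bin_width GC bin width (shared with the peak caller).
#' @param fragment_length ChIP fragment length; reads are placed so that
#'   extension to this length covers the site.
#' @param read_length mapped read length.
#' @param n_control_artifacts number of artifact spike regions in the
#'   control sample.
#' @param artifact_reads expected reads per artifact spike.
#' @param access_meanlog,access_sdlog latent log-normal accessibility score.
#' @param access_multipliers occupancy multipliers for low/moderate/high
#'   accessibility classes (set all to 1 to decouple).
#' @param core_coupling,flank_coupling intercept/slope pairs for the
#'   probability (at affinity quantile q) of a preferred core and of
#'   consensus flanking bases.
#' @param n_repeat_tracts,repeat_length number and length of duplicated
#'   (non-uniquely-mappable) tracts per genome.
#' @param n_tss number of synthetic TSS annotations.
#' @param seed integer seed; all generation is deterministic given it.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_chroms = 3L,
                             chrom_length = 2e6,
                             gc_levels = c(0.375, 0.475, 0.575),
                             n_true_sites = 5000L,
                             affinity_sdlog = 1.5,
                             dose_factor = 4,
                             n_fg_reads = 350000L,
                             bg_mu_intercept = 0.5,
                             bg_mu_slope = 3,
                             bg_size = 2,
                             bg_block = 2000L,
                             window_size = 200L,
                             gc_bin_width = 0.05,
                             fragment_length = 200L,
                             read_length = 36L,
                             n_control_artifacts = 20L,
                             artifact_reads = 150,
                             access_meanlog = 0.35,
                             access_sdlog = 0.8,
                             access_multipliers = c(low = 0.3, moderate = 1,
                                                    high = 3),
                             core_coupling = c(0.3, 0.65),
                             flank_coupling = c(0.4, 0.55),
                             n_repeat_tracts = 30L,
                             repeat_length = 2000L,
                             n_tss = 300L,
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_chroms <- as.integer(n_chroms)
  cfg$chrom_length <- as.integer(chrom_length)
  cfg$n_true_sites <- as.integer(n_true_sites)
  cfg$n_fg_reads <- as.integer(n_fg_reads)
  cfg$seed <- as.integer(seed)
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length >= 1000,
            all(gc_levels > 0 & gc_levels < 1),
            cfg$n_true_sites >= 0, affinity_sdlog >= 0,
            dose_factor > 0,
            bg_mu_intercept + bg_mu_slope * min(gc_levels) > 0,
            bg_size > 0, window_size > 0, fragment_length > 0,
            read_length > 0, read_length <= fragment_length,
            length(access_multipliers) == 3, all(access_multipliers > 0))
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_chroms, " x ",
      format(x$chrom_length, big.mark = ","), " bp, ",
      x$n_true_sites, " sites, dose factor ", x$dose_factor,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# GC bin helpers shared by generator and background model ----------------

#' @keywords internal
gc_bin_index <- function(gc, bin_width) {
  n_bins <- ceiling(1 / bin_width)
  idx <- floor(gc / bin_width) + 1L
  idx[gc >= 1] <- n_bins
  as.integer(pmin(pmax(idx, 1L), n_bins))
}

#' @keywords internal
gc_bin_mid <- function(idx, bin_width) (idx - 0.5) * bin_width

#' Background NB mean for a GC bin under a synthetic configuration
#' @keywords internal
synthetic_bg_mu <- function(config, gc) {
  idx <- gc_bin_index(gc, config$gc_bin_width)
  config$bg_mu_intercept + config$bg_mu_slope *
    gc_bin_mid(idx, config$gc_bin_width)
}

# Genome simulation ------------------------------------------------------

#' Simulate a genome with planted binding sites
#'
#' Generates chromosome sequences with piecewise-constant GC along each
#' chromosome, plants an 8-base motif word (consensus-flanked E-box) at each
#' true binding site, inserts duplicated repeat tracts marked non-mappable,
#' and assigns per-site affinities and accessibility classes. Deterministic
#' given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `genome` (a [genome] object) and `truth`
#'   (class `"ground_truth"`): `sites` (E-box `GRanges` with affinity,
#'   accessibility, planted word, effective occupancy weight and its
#'   quantile), `artifacts` (`GRanges` of control artifact loci), and
#'   `accessibility` (score table for every CAGCTG E-box).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_chr <- config$n_chroms
  len <- config$chrom_length
  chroms <- paste0("chr", seq_len(n_chr))
  bases <- c("A", "C", "G", "T")

  seqs <- character(n_chr)
  mask <- vector("list", n_chr)
  gc_levels <- rep(config$gc_levels, length.out = 3L)
  for (i in seq_len(n_chr)) {
    seg <- ceiling(len / 3)
    gc_vec <- rep(gc_levels, times = c(seg, seg, len - 2 * seg))
    is_gc <- runif(len) < gc_vec
    half <- runif(len) < 0.5
    code <- ifelse(is_gc, ifelse(half, 2L, 3L), ifelse(half, 1L, 4L))
    seqs[i] <- paste0(bases[code], collapse = "")
    mask[[i]] <- rep(TRUE, len)
  }
  names(mask) <- chroms

  # duplicated repeat tracts: copy a donor segment; donor and copies are
  # non-uniquely mappable
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rep_tracts <- NULL
  if (config$n_repeat_tracts > 0) {
    rl <- config$repeat_length
    donor_chr <- 1L
    donor_start <- sample.int(len - rl, 1L)
    donor <- chars[[donor_chr]][donor_start:(donor_start + rl - 1L)]
    tr_chr <- sample.int(n_chr, config$n_repeat_tracts, replace = TRUE)
    tr_start <- sample.int(len - rl, config$n_repeat_tracts)
    for (j in seq_len(config$n_repeat_tracts)) {
      idx <- tr_start[j]:(tr_start[j] + rl - 1L)
      chars[[tr_chr[j]]][idx] <- donor
      mask[[tr_chr[j]]][idx] <- FALSE
    }
    mask[[donor_chr]][donor_start:(donor_start + rl - 1L)] <- FALSE
    rep_tracts <- GRanges(chroms[c(donor_chr, tr_chr)],
                          IRanges(start = c(donor_start, tr_start),
                                  width = rl))
  }

  # true binding sites: uniform over mappable sequence, kept >= 10 bp apart
  # so planted words stay intact
  n_sites <- config$n_true_sites
  margin <- 200L
  site_chr <- integer(0); site_pos <- integer(0)
  while (length(site_pos) < n_sites) {
    need <- n_sites - length(site_pos)
    c_i <- sample.int(n_chr, 2L * need + 10L, replace = TRUE)
    p_i <- sample(seq.int(margin, len - margin), 2L * need + 10L,
                  replace = TRUE)
    ok <- vapply(seq_along(c_i),
                 function(k) all(mask[[c_i[k]]][(p_i[k] - 5L):(p_i[k] + 10L)]),
                 logical(1))
    c_i <- c_i[ok]; p_i <- p_i[ok]
    site_chr <- c(site_chr, c_i); site_pos <- c(site_pos, p_i)
    o <- order(site_chr, site_pos)
    site_chr <- site_chr[o]; site_pos <- site_pos[o]
    keep <- c(TRUE, !(diff(site_pos) < 10L & diff(site_chr) == 0L))
    site_chr <- site_chr[keep]; site_pos <- site_pos[keep]
    if (length(site_pos) > n_sites) {
      pick <- sort(sample.int(length(site_pos), n_sites))
      site_chr <- site_chr[pick]; site_pos <- site_pos[pick]
    }
  }

  affinity <- if (config$affinity_sdlog > 0)
    rlnorm(n_sites, meanlog = 0, sdlog = config$affinity_sdlog)
  else rep(1, n_sites)
  access_score <- rlnorm(n_sites, config$access_meanlog, config$access_sdlog)
  access_class <- cut(access_score, c(0, 1, 2, Inf),
                      labels = c("low", "moderate", "high"), right = TRUE)
  mult <- config$access_multipliers[as.integer(access_class)]
  eff <- affinity * mult
  q <- (rank(eff, ties.method = "first") - 0.5) / max(n_sites, 1L)

  # plant an RRCAGSTG-style 8-mer: flanks R R, core CAGSTG; with probability
  # decreasing in affinity quantile the core's internal dinucleotide is
  # randomized instead of the preferred G/S
  p_core <- pmin(config$core_coupling[1] + config$core_coupling[2] * q, 1)
  p_flank <- pmin(config$flank_coupling[1] + config$flank_coupling[2] * q, 1)
  words <- character(n_sites)
  for (i in seq_len(n_sites)) {
    fl <- ifelse(runif(2) < p_flank[i],
                 sample(c("A", "G"), 2, replace = TRUE),
                 sample(bases, 2, replace = TRUE))
    if (runif(1) < p_core[i]) {
      nn <- if (runif(1) < 0.5) c("G", "C") else c("G", "G")
    } else {
      nn <- sample(bases, 2, replace = TRUE)
    }
    w <- c(fl, "C", "A", nn, "T", "G")
    words[i] <- paste0(w, collapse = "")
    # e-box occupies positions p .. p+5, flanks at p-2, p-1
    p <- site_pos[i]
    chars[[site_chr[i]]][(p - 2L):(p + 5L)] <- w
  }

  # control artifact loci (mappable, away from true sites)
  n_art <- config$n_control_artifacts
  art <- GRanges()
  if (n_art > 0) {
    art_chr <- sample.int(n_chr, n_art, replace = TRUE)
    art_pos <- sample(seq.int(margin, len - margin), n_art)
    art <- GRanges(chroms[art_chr], IRanges(start = art_pos, width = 1L))
  }

  tss <- GRanges(chroms[sample.int(n_chr, config$n_tss, replace = TRUE)],
                 IRanges(start = sample.int(len, config$n_tss), width = 1L))

  seqs <- vapply(chars, paste0, character(1), collapse = "")
  names(seqs) <- chroms
  gen <- genome(seqs,
                mappability = methods::as(lapply(mask, Rle), "RleList"),
                tss = sort(tss))

  sites <- GRanges(chroms[site_chr], IRanges(start = site_pos, width = 6L),
                   seqinfo = genome_seqinfo(gen))
  mcols(sites)$affinity <- affinity
  mcols(sites)$access_score <- access_score
  mcols(sites)$access_class <- as.character(access_class)
  mcols(sites)$eff <- eff
  mcols(sites)$q <- q
  mcols(sites)$word <- words
  mcols(sites)$core <- substr(words, 3L, 8L)

  # accessibility score table for every CAGCTG E-box in the genome: planted
  # CAGCTG sites keep their latent score, all others draw independent scores
  cag <- scan_eboxes(gen, exclude = NULL, exclude_chroms = character(0))
  cag <- cag[mcols(cag)$variant == "GC"]
  sc <- rlnorm(length(cag), config$access_meanlog, config$access_sdlog)
  hit <- findOverlaps(cag, sites, type = "equal")
  sc[queryHits(hit)] <- access_score[subjectHits(hit)]
  acc_tab <- data.frame(chrom = as.character(seqnames(cag)),
                        start = start(cag) - 1L,
                        score = sc, stringsAsFactors = FALSE)

  truth <- structure(list(sites = sites, artifacts = art,
                          accessibility = acc_tab,
                          config = config),
                     class = "ground_truth")
  list(genome = gen, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$sites), " sites, ",
      length(x$artifacts), " control artifacts, ",
      nrow(x$accessibility), " CAGCTG accessibility scores\n", sep = "")
  invisible(x)
}

# Read simulation --------------------------------------------------------

#' Simulate a ChIP read sample
#'
#' Foreground reads are allocated to true sites in proportion to
#' affinity x accessibility multiplier (scaled by `dose_factor` for the
#' overexpressed sample) and placed strand-split around the site so that
#' extension to `fragment_length` covers it. Background reads are drawn per
#' GC window from the configured Gamma-Poisson (negative binomial) law;
#' windows in non-mappable tracts receive none. The control sample contains
#' background plus `n_control_artifacts` spike regions at the fixed loci in
#' `truth$artifacts`. Deterministic given `config$seed` and the sample label.
#'
#' @param genome genome from [simulate_genome()].
#' @param truth ground truth from [simulate_genome()].
#' @param config the [synthetic_config()] used to build the genome.
#' @param sample one of `"endogenous"`, `"overexpressed"`, `"control"`.
#' @return Stranded `GRanges` of mapped reads with a `origin` metadata
#'   column (`"foreground"`, `"background"` or `"artifact"`).
#' @export
simulate_reads <- function(genome, truth, config,
                           sample = c("endogenous", "overexpressed",
                                      "control")) {
  sample <- match.arg(sample)
  stopifnot(inherits(config, "synthetic_config"))
  offset <- c(endogenous = 101L, overexpressed = 202L, control = 303L)
  set.seed(config$seed * 31L + offset[[sample]])

  lens <- chrom_lengths(genome)
  rl <- config$read_length
  frag <- config$fragment_length

  place_at <- function(chr, center, k_per) {
    # k_per reads at each center, strand-split so extension covers center
    chr <- rep(chr, k_per)
    center <- rep(center, k_per)
    n <- length(center)
    if (n == 0) return(GRanges())
    lo <- max(1L, round(0.1 * frag)); hi <- round(0.9 * frag)
    off <- sample(seq.int(lo, hi), n, replace = TRUE)
    plus <- runif(n) < 0.5
    st <- ifelse(plus, center - off, center + off - rl + 1L)
    st <- pmax(1L, pmin(st, lens[chr] - rl + 1L))
    GRanges(chr, IRanges(start = st, width = rl),
            strand = ifelse(plus, "+", "-"))
  }

  out <- list()

  if (sample != "control" && config$n_true_sites > 0 &&
      config$n_fg_reads > 0) {
    n_fg <- round(config$n_fg_reads *
                    if (sample == "overexpressed") config$dose_factor else 1)
    eff <- mcols(truth$sites)$eff
    counts <- as.integer(rmultinom(1, size = n_fg, prob = eff / sum(eff)))
    centers <- start(truth$sites) + 2L
    fg <- place_at(as.character(seqnames(truth$sites)), centers, counts)
    mcols(fg)$origin <- "foreground"
    out$fg <- fg
  }

  # background: per-window NB counts via block-persistent Gamma rates
  wins <- gc_windows(genome, config$window_size)
  map_frac <- window_map_fraction(genome, wins)
  usable <- !is.na(mcols(wins)$gc) & map_frac >= 0.5
  mu <- synthetic_bg_mu(config, mcols(wins)$gc)
  win_per_block <- max(1L, round(config$bg_block / config$window_size))
  chr_of <- as.character(seqnames(wins))
  idx_in_chr <- unlist(lapply(rle(chr_of)$lengths, seq_len))
  block_id <- paste0(chr_of, "_", (idx_in_chr - 1L) %/% win_per_block)
  ub <- unique(block_id)
  g_mult <- stats::setNames(rgamma(length(ub), shape = config$bg_size,
                                   rate = config$bg_size), ub)
  lam <- mu * g_mult[block_id]
  k <- integer(length(wins))
  k[usable] <- rpois(sum(usable), lam[usable])
  nz <- which(k > 0)
  if (length(nz)) {
    anchors <- unlist(lapply(nz, function(i) {
      start(wins)[i] + sample.int(width(wins)[i], k[i], replace = TRUE) - 1L
    }))
    chr_bg <- rep(chr_of[nz], k[nz])
    n <- length(anchors)
    plus <- runif(n) < 0.5
    st <- ifelse(plus, anchors, anchors + frag - rl)
    st <- pmax(1L, pmin(st, lens[chr_bg] - rl + 1L))
    bg <- GRanges(chr_bg, IRanges(start = st, width = rl),
                  strand = ifelse(plus, "+", "-"))
    mcols(bg)$origin <- "background"
    out$bg <- bg
  }

  if (sample == "control" && length(truth$artifacts) > 0) {
    k_art <- rpois(length(truth$artifacts), config$artifact_reads)
    ar <- place_at(as.character(seqnames(truth$artifacts)),
                   start(truth$artifacts), k_art)
    mcols(ar)$origin <- "artifact"
    out$art <- ar
  }

  reads <- do.call(c, unname(out))
  if (is.null(reads)) reads <- GRanges()
  seqlengths(reads) <- lens[seqlevels(reads)]
  sort(reads, ignore.strand = TRUE)
}

# Fixture I/O ------------------------------------------------------------

#' Write a simulated fixture to disk
#'
#' Writes the genome (soft-masked FASTA), one BED6 file per read sample,
#' TSS BED, and tab-delimited truth tables (sites, artifacts, accessibility
#' scores), all reloadable with the package's readers.
#'
#' @param genome,truth from [simulate_genome()].
#' @param reads named list of read `GRanges` (names become file stems).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(genome, truth, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "genome.fa")
  write_genome_fasta(genome, f); files <- c(files, f)
  if (!is.null(genome$tss)) {
    f <- file.path(dir, "tss.bed")
    write_bed(genome$tss, f); files <- c(files, f)
  }
  for (nm in names(reads)) {
    f <- file.path(dir, paste0("reads_", nm, ".bed"))
    write_bed(reads[[nm]], f); files <- c(files, f)
  }
  sites <- truth$sites
  site_df <- data.frame(chrom = as.character(seqnames(sites)),
                        start = start(sites) - 1L, end = end(sites),
                        as.data.frame(mcols(sites)),
                        stringsAsFactors = FALSE)
  f <- file.path(dir, "truth_sites.tsv")
  write_tsv(site_df, f); files <- c(files, f)
  if (length(truth$artifacts)) {
    art_df <- data.frame(chrom = as.character(seqnames(truth$artifacts)),
                         start = start(truth$artifacts) - 1L,
                         end = end(truth$artifacts))
    f <- file.path(dir, "truth_artifacts.tsv")
    write_tsv(art_df, f); files <- c(files, f)
  }
  f <- file.path(dir, "accessibility.tsv")
  write_tsv(truth$accessibility, f); files <- c(files, f)
  invisible(files)
}
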