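# E-box scanning and occupancy analyses -----------------------------------

#' @keywords internal
revcomp_chr <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Canonical E-box variant class of an internal dinucleotide
#'
#' The CANNTG pattern is its own reverse complement as a pattern class, so a
#' variant and its reverse complement (e.g. CACCTG / CAGGTG) describe the
#' same site; the class label is the lexicographically smaller of the
#' internal dinucleotide and its reverse complement.
#'
#' @param nn character vector of internal dinucleotides (e.g. `"GC"`).
#' @return Character vector of canonical class labels.
#' @export
ebox_variant_class <- function(nn) {
  nn <- toupper(nn)
  rc <- revcomp_chr(nn)
  ifelse(nn <= rc, nn, rc)
}

#' Scan a genome for E-boxes (CANNTG)
#'
#' Reports every forward-strand CANNTG match exactly once (the pattern class
#' is reverse-complement symmetric, so a forward scan is complete). Sites on
#' excluded chromosomes or overlapping supplied control-peak intervals are
#' dropped. Each site carries its internal-dinucleotide variant, canonical
#' variant class, flanking sequence, and a mappability flag (`TRUE` when the
#' site's +/-200-base window is fully mappable and inside the chromosome).
#'
#' @param genome a [genome] object.
#' @param exclude optional `GRanges` (e.g. control peaks); overlapping sites
#'   are dropped.
#' @param exclude_chroms chromosome names to skip entirely.
#' @param flank flanking bases recorded on each side of the hexamer.
#' @param mappable_window half-width of the window used for the
#'   mappability flag.
#' @return `GRanges` of 6-base sites with metadata columns `nn`, `variant`,
#'   `flanks`, `mappable`.
#' @export
scan_eboxes <- function(genome, exclude = NULL,
                        exclude_chroms = c("chrX", "chrY"),
                        flank = 6L, mappable_window = 200L) {
  chroms <- setdiff(names(genome$seq), exclude_chroms)
  mp <- genome_mappability(genome)
  si <- genome_seqinfo(genome)
  out <- list()
  for (chr in chroms) {
    subject <- genome$seq[[match(chr, names(genome$seq))]]
    m <- matchPattern("CANNTG", subject, fixed = FALSE)
    if (length(m) == 0) next
    st <- start(m)
    seqs <- as.character(m)
    # fixed = FALSE lets N in the subject match too; require exact C,A,T,G
    # at the fixed positions and ACGT at the internal ones
    okpat <- grepl("^CA[ACGT][ACGT]TG$", seqs)
    st <- st[okpat]; seqs <- seqs[okpat]
    if (length(st) == 0) next
    nn <- substr(seqs, 3L, 4L)
    len <- length(subject)
    fl_start <- pmax(st - flank, 1L)
    fl_end <- pmin(st + 5L + flank, len)
    flanks <- as.character(Views(subject, start = fl_start, end = fl_end))
    win_ok <- st - mappable_window >= 1L & st + 5L + mappable_window <= len
    mappable <- rep(FALSE, length(st))
    if (any(win_ok)) {
      v <- Views(mp[[chr]] * 1L,
                 start = st[win_ok] - mappable_window,
                 end = st[win_ok] + 5L + mappable_window)
      mappable[win_ok] <- as.numeric(IRanges::viewMins(v)) == 1
    }
    gr <- GRanges(chr, IRanges(start = st, width = 6L), seqinfo = si)
    mcols(gr)$nn <- nn
    mcols(gr)$variant <- ebox_variant_class(nn)
    mcols(gr)$flanks <- flanks
    mcols(gr)$mappable <- mappable
    out[[chr]] <- gr
  }
  if (length(out) == 0) {
    gr <- GRanges()
    mcols(gr)$nn <- character(0)
    mcols(gr)$variant <- character(0)
    mcols(gr)$flanks <- character(0)
    mcols(gr)$mappable <- logical(0)
    return(gr)
  }
  gr <- do.call(c, unname(out))
  if (!is.null(exclude) && length(exclude))
    gr <- gr[!overlapsAny(gr, exclude, ignore.strand = TRUE)]
  gr
}

#' Rank E-boxes by coverage significance
#'
#' Each site's coverage is the maximum depth over its 6 bases; its p-value
#' comes from the background model's GC bin at the site's window. Sites are
#' sorted by ascending p-value, ties broken by descending coverage then
#' coordinate; zero-coverage sites have p = 1 and sort last.
#'
#' @param sites E-box `GRanges` from [scan_eboxes()].
#' @param coverage a [coverage_track] for the sample.
#' @param model the sample's `nbgc_model`.
#' @param genome the [genome].
#' @return The sites, re-ordered, with added metadata columns `coverage`,
#'   `p_value`, `rank`.
#' @export
rank_eboxes <- function(sites, coverage, model, genome) {
  if (length(sites) == 0) return(sites)
  cov <- max_depth_at(coverage, sites)
  wt <- window_table(NULL, genome, model$window_size, model$gc_bin_width)
  wins <- wt$windows
  chr_names <- as.character(seqnames(wins))
  # index of the tile containing each site start, per chromosome
  offs <- c(0L, cumsum(rle(chr_names)$lengths))
  names(offs) <- c(rle(chr_names)$values, "_end")
  site_chr <- as.character(seqnames(sites))
  tile_idx <- offs[site_chr] + (start(sites) - 1L) %/% model$window_size + 1L
  bins <- wt$bins[tile_idx]
  pv <- rep(1, length(sites))
  hb <- !is.na(bins) & cov > 0
  if (any(hb)) {
    mu <- model$mu[bins[hb]]; size <- model$size[bins[hb]]
    pv[hb] <- ifelse(is.infinite(size),
                     ppois(cov[hb] - 1, mu, lower.tail = FALSE),
                     pnbinom(cov[hb] - 1, size = size, mu = mu,
                             lower.tail = FALSE))
  }
  mcols(sites)$coverage <- cov
  mcols(sites)$p_value <- pv
  o <- order(pv, -cov, match(site_chr, seqlevels(sites)), start(sites))
  sites <- sites[o]
  mcols(sites)$rank <- seq_along(sites)
  sites
}

#' E-box variant distribution by rank bin
#'
#' Partitions ranked E-boxes into bins (top `bin_edges[1]`, then up to
#' `bin_edges[2]`, etc., until all sites are included) and tabulates the
#' proportion of each canonical variant class within each bin, plus a
#' genome-background row tabulated over all sites.
#'
#' @param sites ranked E-box `GRanges` from [rank_eboxes()].
#' @param bin_edges increasing rank boundaries; defaults to
#'   1000 x 10^(0, 1, 2, ...) until the site count is exceeded.
#' @return An object of class `"ebox_bin_table"`: proportions matrix
#'   (rows = bins plus `"background"`, columns = variant classes) with bin
#'   sizes as an attribute.
#' @export
variant_distribution_by_bin <- function(sites, bin_edges = NULL) {
  n <- length(sites)
  if (n == 0) stop("no sites")
  if (is.null(bin_edges)) {
    bin_edges <- 1000 * 10^(0:10)
    bin_edges <- bin_edges[bin_edges < n]
  }
  bin_edges <- sort(unique(c(bin_edges[bin_edges < n], n)))
  lower <- c(0, utils::head(bin_edges, -1))
  classes <- sort(unique(mcols(sites)$variant))
  rows <- lapply(seq_along(bin_edges), function(i) {
    sel <- mcols(sites)$rank > lower[i] & mcols(sites)$rank <= bin_edges[i]
    tab <- table(factor(mcols(sites)$variant[sel], levels = classes))
    as.numeric(tab) / max(sum(tab), 1L)
  })
  bg <- table(factor(mcols(sites)$variant, levels = classes))
  bg <- as.numeric(bg) / sum(bg)
  mat <- rbind(do.call(rbind, rows), background = bg)
  colnames(mat) <- classes
  labels <- sprintf("%d-%d", lower + 1, bin_edges)
  labels[1] <- sprintf("top %d", bin_edges[1])
  rownames(mat) <- c(labels, "background")
  structure(mat, bin_sizes = c(bin_edges - lower, n),
            class = c("ebox_bin_table", class(mat)))
}

#' @export
print.ebox_bin_table <- function(x, ...) {
  cat("<ebox_bin_table> variant proportions by rank bin\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @keywords internal
matches_degenerate <- function(strings, pattern) {
  # does each string contain `pattern` (IUPAC degenerate) on either strand?
  pat <- DNAString(pattern)
  subj <- DNAStringSet(strings)
  fwd <- vcountPattern(pat, subj, fixed = FALSE) > 0
  rev <- vcountPattern(reverseComplement(pat), subj, fixed = FALSE) > 0
  fwd | rev
}

#' Consensus-site flag for E-boxes
#'
#' Flags E-boxes whose local context matches a degenerate consensus such as
#' RRCAGSTG on either strand. The pattern must contain the CANNTG core; the
#' site's recorded flanking sequence is scanned.
#'
#' @param sites E-box `GRanges` from [scan_eboxes()].
#' @param pattern IUPAC degenerate consensus containing the E-box core.
#' @return Logical vector, one flag per site.
#' @export
ebox_matches_consensus <- function(sites, pattern = "RRCAGSTG") {
  if (length(sites) == 0) return(logical(0))
  matches_degenerate(mcols(sites)$flanks, pattern)
}

#' Coverage CCDF over consensus E-box sites
#'
#' Computes, per sample, the proportion of sites with coverage greater than
#' each threshold on a log2-spaced grid, after sub-sampling all samples'
#' reads to the common minimum so coverage is comparable. Only sites whose
#' +/-200-base window is uniquely mappable are included. The complementary
#' site set (E-boxes not matching the consensus) is evaluated alongside for
#' comparison.
#'
#' @param sites E-box `GRanges` from [scan_eboxes()].
#' @param reads named list of read `GRanges`, one per sample.
#' @param genome the [genome].
#' @param pattern degenerate consensus defining the site class.
#' @param grid coverage thresholds; default `2^(0:10) - 1` (0, 1, 3, ...).
#' @param extension read extension length.
#' @param seed sub-sampling seed.
#' @return An object of class `"ccdf_set"`: list with `grid` and a
#'   `ccdf[[sample]][[class]]` table for `consensus` and `other` sites.
#' @export
coverage_ccdf <- function(sites, reads, genome, pattern = "RRCAGSTG",
                          grid = 2^(0:10) - 1, extension = 200L,
                          seed = 1L) {
  stopifnot(is.list(reads), length(reads) >= 1, !is.null(names(reads)))
  sites <- sites[mcols(sites)$mappable]
  is_cons <- ebox_matches_consensus(sites, pattern)
  if (!any(is_cons))
    stop("pattern ", pattern, " matches no mappable site")
  n <- min(vapply(reads, length, integer(1)))
  ccdf <- list()
  for (k in seq_along(reads)) {
    r <- subsample_reads(reads[[k]], n, seed = seed + k)
    cov <- build_coverage(r, genome, total_length = extension)
    depth <- max_depth_at(cov, sites)
    ccdf[[names(reads)[k]]] <- list(
      consensus = ccdf_at(depth[is_cons], grid),
      other = if (any(!is_cons)) ccdf_at(depth[!is_cons], grid) else NULL)
  }
  structure(list(grid = grid, ccdf = ccdf, pattern = pattern,
                 n_sites = c(consensus = sum(is_cons),
                             other = sum(!is_cons)),
                 n_reads_each = n),
            class = "ccdf_set")
}

#' @keywords internal
ccdf_at <- function(values, grid) {
  vapply(grid, function(x) mean(values > x), numeric(1))
}

#' @export
print.ccdf_set <- function(x, ...) {
  cat("<ccdf_set> ", paste(names(x$ccdf), collapse = ", "),
      "; ", x$n_reads_each, " reads per sample\n", sep = "")
  for (nm in names(x$ccdf)) {
    cat("  ", nm, ":\n", sep = "")
    tab <- do.call(rbind, x$ccdf[[nm]])
    colnames(tab) <- paste0(">", x$grid)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Accessibility class of a score
#'
#' Scores are assigned to half-open intervals: low `(0, 1]`, moderate
#' `(1, 2]`, high `(2, Inf)`; a score of exactly 1 is low and exactly 2 is
#' moderate. Non-positive or missing scores are `"unknown"`.
#'
#' @param score numeric accessibility scores.
#' @return Character vector of class labels.
#' @export
accessibility_class <- function(score) {
  out <- rep("unknown", length(score))
  ok <- !is.na(score) & score > 0
  out[ok & score <= 1] <- "low"
  out[ok & score > 1 & score <= 2] <- "moderate"
  out[ok & score > 2] <- "high"
  out
}

#' Accessibility-stratified coverage CCDF over CAGCTG E-boxes
#'
#' Joins per-E-box accessibility scores to CAGCTG-class sites by position,
#' stratifies them into low/moderate/high classes, and computes per-class
#' coverage CCDFs for each sample after equal-count read sub-sampling.
#' Sites without a score are labeled unknown and excluded (their count is
#' reported via a message).
#'
#' @param sites E-box `GRanges` from [scan_eboxes()].
#' @param scores data.frame with columns `chrom`, `start` (0-based E-box
#'   start) and `score`.
#' @param reads named list of read `GRanges`, one per sample.
#' @param genome the [genome].
#' @param grid coverage thresholds.
#' @param extension read extension length.
#' @param seed sub-sampling seed.
#' @return An object of class `"ccdf_set"` whose per-sample tables have one
#'   row per accessibility class.
#' @export
accessibility_ccdf <- function(sites, scores, reads, genome,
                               grid = 2^(0:10) - 1, extension = 200L,
                               seed = 1L) {
  sites <- sites[mcols(sites)$variant == "GC" & mcols(sites)$mappable]
  key_site <- paste0(as.character(seqnames(sites)), ":", start(sites) - 1L)
  key_sc <- paste0(scores$chrom, ":", scores$start)
  score <- scores$score[match(key_site, key_sc)]
  cls <- accessibility_class(score)
  n_unknown <- sum(cls == "unknown")
  if (n_unknown > 0)
    message(n_unknown, " site(s) without accessibility score excluded")
  keep <- cls != "unknown"
  sites <- sites[keep]; cls <- cls[keep]
  if (length(sites) == 0) stop("no scored CAGCTG sites")
  n <- min(vapply(reads, length, integer(1)))
  ccdf <- list()
  for (k in seq_along(reads)) {
    r <- subsample_reads(reads[[k]], n, seed = seed + k)
    cov <- build_coverage(r, genome, total_length = extension)
    depth <- max_depth_at(cov, sites)
    ccdf[[names(reads)[k]]] <- lapply(
      stats::setNames(c("low", "moderate", "high"),
                      c("low", "moderate", "high")),
      function(cl) ccdf_at(depth[cls == cl], grid))
  }
  structure(list(grid = grid, ccdf = ccdf, pattern = "CAGCTG",
                 n_sites = table(cls), n_reads_each = n),
            class = "ccdf_set")
}
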