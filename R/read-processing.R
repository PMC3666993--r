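#' Remove duplicate reads
#'
#' Retains at most one read per (chromosome, start, end, strand) key, keeping
#' the first occurrence in input order. Identical mapped spans are the
#' working proxy for PCR-amplification duplicates.
#'
#' @param reads [GenomicRanges::GRanges] of mapped reads.
#' @return `GRanges` with duplicates removed; idempotent.
#' @export
deduplicate_reads <- function(reads) {
  reads[!BiocGenerics::duplicated(granges(reads))]
}

#' Drop reads on excluded chromosomes
#'
#' @param reads `GRanges` of mapped reads.
#' @param names chromosome names to exclude (e.g. sex chromosomes).
#' @return `GRanges` with no read on any excluded chromosome.
#' @export
exclude_chromosomes <- function(reads, names) {
  if (length(names) == 0) return(reads)
  reads[!(as.character(seqnames(reads)) %in% names)]
}

#' Extend reads in sequencing orientation
#'
#' Each read is extended 3'-ward to `total_length` bases: a `+` read keeps
#' its start, a `-` read keeps its end. Extended intervals are clipped to
#' chromosome bounds (requires seqlengths on `reads` or a `genome`); reads
#' already at least `total_length` long are returned unchanged.
#'
#' @param reads stranded `GRanges`.
#' @param total_length target length in bases.
#' @param genome optional [genome] object supplying chromosome lengths.
#' @return `GRanges` of extended intervals (strand preserved).
#' @export
extend_reads <- function(reads, total_length = 200L, genome = NULL) {
  stopifnot(total_length > 0)
  if (length(reads) == 0) return(reads)
  if (any(as.character(strand(reads)) == "*"))
    stop("cannot extend unstranded reads")
  if (!is.null(genome))
    seqlengths(reads) <- chrom_lengths(genome)[seqlevels(reads)]
  out <- suppressWarnings(
    resize(reads, width = pmax(width(reads), total_length), fix = "start"))
  if (!anyNA(seqlengths(out)))
    out <- GenomicRanges::trim(out)
  else {
    # no chromosome lengths known: clip at the left edge only
    start(out) <- pmax(start(out), 1L)
  }
  out
}

#' Coverage track
#'
#' Per-base read depth after directional extension. The object retains the
#' extended read intervals (needed by the background model, which counts
#' extended-read anchors in GC windows) together with the depth profile.
#'
#' @param reads deduplicated stranded `GRanges` of mapped reads.
#' @param genome a [genome] object (defines chromosome bounds).
#' @param total_length extension length in bases.
#' @return An object of class `"coverage_track"`: list with `depth`
#'   (integer [IRanges::RleList]), `reads_extended` (`GRanges`),
#'   `total_reads`, `extension`.
#' @export
build_coverage <- function(reads, genome, total_length = 200L) {
  lens <- chrom_lengths(genome)
  bad <- setdiff(as.character(seqnames(reads)), names(lens))
  if (length(bad))
    stop("reads on unknown chromosome(s): ", paste(unique(bad), collapse = ", "))
  reads <- GRanges(seqnames(reads), IRanges(start(reads), end(reads)),
                   strand = strand(reads),
                   seqinfo = genome_seqinfo(genome))
  ext <- extend_reads(reads, total_length = total_length, genome = genome)
  depth <- coverage(ext)
  structure(list(depth = depth,
                 reads_extended = ext,
                 total_reads = length(reads),
                 extension = as.integer(total_length)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$depth, function(r) sum(as.numeric(runValue(r)) *
                                               runLength(r)), numeric(1)))
  cat("<coverage_track> ", x$total_reads, " reads extended to ", x$extension,
      " bases; total depth mass ", format(tot, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Sub-sample reads without replacement
#'
#' Draws exactly `n` reads uniformly without replacement; used to equalize
#' read counts between samples before comparing coverage or peak heights.
#'
#' @param reads `GRanges` of mapped reads.
#' @param n number of reads to keep (`n <= length(reads)`).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return `GRanges` of `n` reads (input order preserved).
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  if (n > length(reads))
    stop("cannot sub-sample ", n, " from ", length(reads), " reads")
  if (n == length(reads)) return(reads)
  set.seed(as.integer(seed))
  idx <- sort(sample.int(length(reads), size = n, replace = FALSE))
  reads[idx]
}
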