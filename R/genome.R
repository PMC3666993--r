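#' Genome object
#'
#' Bundles chromosome sequences with an optional per-base mappability mask
#' and an optional set of transcription start sites. Sequences are stored
#' uppercase; the mappability mask records which bases are uniquely mappable
#' (in real data this is carried by FASTA soft-masking, in synthetic data it
#' is set directly by the generator).
#'
#' @param sequences named [Biostrings::DNAStringSet] or named character
#'   vector of chromosome sequences over A/C/G/T/N.
#' @param mappability optional named [IRanges::RleList] (or list of logical
#'   vectors) with one logical vector per chromosome, `TRUE` = uniquely
#'   mappable. Must match sequence lengths.
#' @param tss optional [GenomicRanges::GRanges] of transcription start sites.
#' @return An object of class `"genome"`.
#' @export
genome <- function(sequences, mappability = NULL, tss = NULL) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (!methods::is(sequences, "DNAStringSet"))
    stop("`sequences` must be a DNAStringSet or named character vector")
  nm <- names(sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all sequences must be named")
  if (anyDuplicated(nm))
    stop("duplicate sequence names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sequences <- DNAStringSet(toupper(sequences))
  names(sequences) <- nm
  if (!is.null(mappability)) {
    mappability <- methods::as(mappability, "RleList")
    if (!setequal(names(mappability), nm))
      stop("mappability names must match sequence names")
    mappability <- mappability[nm]
    if (any(lengths(mappability) != width(sequences)))
      stop("each mappability vector must have the same length as its chromosome")
  }
  if (!is.null(tss)) {
    stopifnot(methods::is(tss, "GRanges"))
    if (!all(as.character(seqnames(tss)) %in% nm))
      stop("tss on chromosomes absent from the genome")
  }
  structure(list(seq = sequences, mappability = mappability, tss = tss),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x$seq), " chromosome(s), ",
      format(sum(width(x$seq)), big.mark = ","), " bases\n", sep = "")
  for (nm in names(x$seq))
    cat("  ", nm, ": ", width(x$seq)[[match(nm, names(x$seq))]], " bp\n", sep = "")
  if (!is.null(x$mappability)) {
    frac <- sum(vapply(x$mappability, function(r) sum(r), numeric(1))) /
      sum(width(x$seq))
    cat("  mappable fraction: ", round(frac, 4), "\n", sep = "")
  }
  if (!is.null(x$tss)) cat("  TSS annotations: ", length(x$tss), "\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a [genome] object.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(width(genome$seq), names(genome$seq))
}

#' Seqinfo for a genome
#' @keywords internal
genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome$seq), seqlengths = chrom_lengths(genome))
}

#' Mappability mask of a genome (all-TRUE when absent)
#' @keywords internal
genome_mappability <- function(genome) {
  if (!is.null(genome$mappability)) return(genome$mappability)
  methods::as(lapply(chrom_lengths(genome),
                     function(n) Rle(TRUE, n)), "RleList")
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased; soft-masked (lowercase) bases are recorded as
#' non-mappable in the genome's mappability mask, following the convention
#' that repeat-masked sequence is not uniquely mappable.
#'
#' @param path FASTA file.
#' @param tss optional [GenomicRanges::GRanges] of TSS to attach.
#' @return A [genome] object.
#' @export
read_genome_fasta <- function(path, tss = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)  # preserves case
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate sequence names in ", path)
  # lowercase = soft-masked = non-mappable
  mask <- lapply(seq_along(raw), function(i) {
    chars <- strsplit(as.character(raw[[i]]), "", fixed = TRUE)[[1]]
    Rle(!(chars %in% c("a", "c", "g", "t", "n")))
  })
  names(mask) <- names(raw)
  seqs <- DNAStringSet(toupper(raw))
  genome(seqs, mappability = methods::as(mask, "RleList"), tss = tss)
}

#' Write a genome to FASTA
#'
#' Non-mappable bases are written lowercase (soft-masked), so the mask
#' round-trips through [read_genome_fasta()].
#'
#' @param genome a [genome] object.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome$seq
  if (!is.null(genome$mappability)) {
    out <- vapply(names(seqs), function(nm) {
      chars <- strsplit(as.character(seqs[[match(nm, names(seqs))]]), "",
                        fixed = TRUE)[[1]]
      m <- as.logical(genome$mappability[[nm]])
      chars[!m] <- tolower(chars[!m])
      paste0(chars, collapse = "")
    }, character(1))
    seqs <- Biostrings::BStringSet(out)  # BString keeps soft-mask case
    names(seqs) <- names(genome$seq)
  }
  writeXStringSet(seqs, filepath = path)
  invisible(NULL)
}

#' Mappable fraction of each window
#' @keywords internal
window_map_fraction <- function(genome, wins) {
  mp <- genome_mappability(genome)
  unlist(lapply(seqlevels(wins), function(chr) {
    w <- wins[seqnames(wins) == chr]
    if (length(w) == 0) return(numeric(0))
    v <- Views(mp[[chr]] * 1L, start = start(w), end = end(w))
    as.numeric(IRanges::viewMeans(v))
  }))
}

#' Per-window GC content of a genome
#'
#' Tiles each chromosome into non-overlapping windows and returns the GC
#' fraction of each window, with N bases excluded from the computation.
#'
#' @param genome a [genome] object.
#' @param window_size window width in bases.
#' @return A [GenomicRanges::GRanges] of windows with metadata column `gc`
#'   (NA where a window contains no A/C/G/T base).
#' @export
gc_windows <- function(genome, window_size = 200L) {
  stopifnot(window_size > 0)
  tiles <- tileGenome(chrom_lengths(genome), tilewidth = window_size,
                      cut.last.tile.in.chrom = TRUE)
  gc <- unlist(lapply(seqlevels(tiles), function(chr) {
    t_chr <- tiles[seqnames(tiles) == chr]
    v <- Views(genome$seq[[match(chr, names(genome$seq))]],
               start = start(t_chr), end = end(t_chr))
    freq <- letterFrequency(v, letters = c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    ifelse(acgt == 0, NA_real_, (freq[, "C"] + freq[, "G"]) / acgt)
  }))
  mcols(tiles)$gc <- gc
  tiles
}
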