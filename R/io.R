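#' Read mapped-read or generic intervals from BED
#'
#' BED coordinates are 0-based half-open on disk; the returned `GRanges` uses
#' the usual 1-based closed convention, so a BED line `chr1 100 136 + `
#' becomes `chr1:101-136:+`. Round-tripping through [write_bed()] reproduces
#' the on-disk coordinates exactly.
#'
#' @param path BED3/BED6 file.
#' @param stranded if `TRUE`, require a strand column (column 6).
#' @return A [GenomicRanges::GRanges]; column 4 (name) and 5 (score) are kept
#'   as metadata columns when present.
#' @export
read_bed <- function(path, stranded = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0 || all(lines == ""))
    return(GRanges())
  keep <- which(lines != "")
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", keep[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("malformed BED line ", keep[bad[1]], ": non-numeric coordinates")
  bad <- which(s < 0 | s >= e)
  if (length(bad))
    stop("invalid interval at line ", keep[bad[1]],
         ": require 0 <= start < end")
  str <- if (any(nf >= 6)) {
    vapply(seq_along(fields), function(i)
      if (nf[i] >= 6) fields[[i]][6] else "*", character(1))
  } else rep("*", length(fields))
  if (stranded && !all(str %in% c("+", "-")))
    stop("stranded = TRUE but strand column missing or not +/- at line ",
         keep[which(!str %in% c("+", "-"))[1]])
  str[!str %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e), strand = str)
  if (any(nf >= 4))
    mcols(gr)$name <- vapply(seq_along(fields), function(i)
      if (nf[i] >= 4) fields[[i]][4] else NA_character_, character(1))
  if (any(nf >= 5))
    mcols(gr)$score <- suppressWarnings(as.numeric(vapply(
      seq_along(fields), function(i)
        if (nf[i] >= 5) fields[[i]][5] else NA_character_, character(1))))
  gr
}

#' Write intervals or peaks to BED
#'
#' Plain `GRanges` are written as BED6 (name/score filled with placeholders
#' when absent). A [ranked_peaks] object is written as BED6+2 with columns
#' name, height (score), strand, p-value, rank; p-values are serialized with
#' 6 significant digits so that values such as 1e-12 round-trip without loss.
#'
#' @param x a `GRanges` or `ranked_peaks` object.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  n_rows <- if (inherits(x, "ranked_peaks")) length(x$peaks) else length(x)
  if (n_rows == 0) {
    file.create(path)
    return(invisible(NULL))
  }
  if (inherits(x, "ranked_peaks")) {
    gr <- x$peaks
    df <- data.frame(
      chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L,
      end = end(gr),
      name = paste0("peak_", mcols(gr)$rank),
      score = mcols(gr)$height,
      strand = ".",
      p_value = formatC(mcols(gr)$p_value, format = "g", digits = 6),
      rank = mcols(gr)$rank,
      stringsAsFactors = FALSE
    )
  } else {
    gr <- x
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
      paste0("iv_", seq_along(gr))
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    df <- data.frame(
      chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L,
      end = end(gr),
      name = nm, score = sc, strand = str,
      stringsAsFactors = FALSE
    )
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read peaks written by [write_bed()]
#'
#' @param path BED6+2 peak file.
#' @return A [ranked_peaks] object (sample label taken from `sample`).
#' @param sample sample label to attach.
#' @export
read_peaks <- function(path, sample = NA_character_) {
  gr <- read_bed(path, stranded = FALSE)
  lines <- readLines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    pk <- GRanges()
    mcols(pk)$height <- numeric(0)
    mcols(pk)$p_value <- numeric(0)
    mcols(pk)$rank <- integer(0)
    return(new_ranked_peaks(pk, sample = sample,
                            total_reads = NA_integer_, p_threshold = NA_real_))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8))
    stop("not a peak BED6+2 file: ", path)
  mcols(gr)$height <- mcols(gr)$score
  mcols(gr)$p_value <- as.numeric(vapply(fields, `[[`, character(1), 7L))
  mcols(gr)$rank <- as.integer(vapply(fields, `[[`, character(1), 8L))
  mcols(gr)$name <- NULL
  mcols(gr)$score <- NULL
  new_ranked_peaks(gr[order(mcols(gr)$rank)], sample = sample,
                   total_reads = NA_integer_, p_threshold = NA_real_)
}

#' Write a coverage track to bedGraph
#'
#' @param coverage a [coverage_track] object.
#' @param path output bedGraph path.
#' @export
write_bedgraph <- function(coverage, path) {
  gr <- methods::as(coverage$depth, "GRanges")
  gr <- gr[mcols(gr)$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(NULL)
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @keywords internal
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
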