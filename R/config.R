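#' Pipeline run configuration
#'
#' Collects the tunable parameters of the analysis pipeline. Defaults follow
#' common single-end ChIP-seq practice: reads extended to 200 bases in
#' sequencing orientation, sex chromosomes excluded, background model windows
#' matched to the extension length so that per-base depth and windowed read
#' counts live on the same scale.
#'
#' @param extension_length total length (bases) each read is extended to.
#' @param exclude_chroms chromosome names dropped at read ingestion.
#' @param window_size background-model window width (bases).
#' @param gc_bin_width width of the GC-fraction bins.
#' @param p_threshold peak-calling p-value threshold.
#' @param control_p lenient threshold for control (artifact) peak calling.
#' @param merge_distance candidate runs closer than this many bases are
#'   merged into one peak.
#' @param rank_bin_width rank bin width for concordance grids and rank-bin
#'   summaries (the full-genome analysis uses 5000; desk-scale fixtures use
#'   smaller bins).
#' @param motif_flank half-width of foreground windows around peak summits.
#' @param seed integer seed controlling all randomized steps.
#' @return An object of class `"run_config"` (a validated list).
#' @export
run_config <- function(extension_length = 200L,
                       exclude_chroms = c("chrX", "chrY"),
                       window_size = extension_length,
                       gc_bin_width = 0.05,
                       p_threshold = 1e-10,
                       control_p = 1e-3,
                       merge_distance = 200L,
                       rank_bin_width = 5000L,
                       motif_flank = 50L,
                       seed = 1L) {
  cfg <- list(extension_length = as.integer(extension_length),
              exclude_chroms = as.character(exclude_chroms),
              window_size = as.integer(window_size),
              gc_bin_width = gc_bin_width,
              p_threshold = p_threshold,
              control_p = control_p,
              merge_distance = as.integer(merge_distance),
              rank_bin_width = as.integer(rank_bin_width),
              motif_flank = as.integer(motif_flank),
              seed = as.integer(seed))
  stopifnot(cfg$extension_length > 0, cfg$window_size > 0,
            cfg$gc_bin_width > 0, cfg$gc_bin_width <= 1,
            cfg$p_threshold > 0, cfg$p_threshold < 1,
            cfg$control_p > 0, cfg$control_p < 1,
            cfg$merge_distance >= 0, cfg$rank_bin_width > 0,
            cfg$motif_flank > 0)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x))
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
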