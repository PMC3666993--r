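#' Run the full two-sample comparison pipeline
#'
#' Orchestrates the analysis end to end: read processing (chromosome
#' exclusion, deduplication, extension, coverage), GC-conditioned NB
#' background fitting and peak calling per sample, control-peak
#' subtraction, rank-cutoff concordance, E-box ranking and variant-by-bin
#' tables, and discriminative motif discovery, writing per-stage outputs
#' and a log under `out_dir`. Deterministic given `config$seed`.
#'
#' @param genome a [genome] object (or path to a FASTA file).
#' @param reads named list with elements `endogenous`, `overexpressed` and
#'   optionally `control`: read `GRanges` or paths to BED files.
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param accessibility optional accessibility-score table (data.frame or
#'   path to a TSV with columns chrom/start/score).
#' @return Invisibly, a list with the fitted models, peak sets, concordance
#'   grid, E-box tables, CCDFs and motif results.
#' @export
run_pipeline <- function(genome, reads, config = run_config(),
                         out_dir = "peakdose_out", accessibility = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("missing genome FASTA: ", genome)
    genome <- read_genome_fasta(genome)
  }
  need <- c("endogenous", "overexpressed")
  if (!all(need %in% names(reads)))
    stop("`reads` must contain elements: ", paste(need, collapse = ", "))
  reads <- lapply(reads, function(r) {
    if (is.character(r)) {
      if (!file.exists(r)) stop("missing read BED: ", r)
      read_bed(r, stranded = TRUE)
    } else r
  })
  if (is.character(accessibility)) accessibility <- read_tsv(accessibility)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con); message(msg)
  }
  stage <- function(name, expr) {
    say("[", name, "] started")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  result <- list(config = config)
  samples <- intersect(c("endogenous", "overexpressed", "control"),
                       names(reads))

  cov <- list(); proc <- list()
  stage("read_processing", {
    for (s in samples) {
      r <- exclude_chromosomes(reads[[s]], config$exclude_chroms)
      r <- deduplicate_reads(r)
      proc[[s]] <- r
      cov[[s]] <- build_coverage(r, genome,
                                 total_length = config$extension_length)
      write_bedgraph(cov[[s]], file.path(out_dir,
                                         paste0("coverage_", s, ".bedGraph")))
      say("  ", s, ": ", length(reads[[s]]), " reads in, ",
          length(r), " after exclusion + dedup")
    }
  })
  result$coverage <- cov

  models <- list(); peaks <- list()
  stage("peak_calling", {
    ctrl_peaks <- NULL
    if ("control" %in% samples) {
      models$control <- fit_background(cov$control, genome,
                                       window_size = config$window_size,
                                       gc_bin_width = config$gc_bin_width)
      ctrl_peaks <- call_peaks(cov$control, models$control, genome,
                               p_threshold = config$control_p,
                               merge_distance = config$merge_distance,
                               sample = "control")
      say("  control: ", n_peaks(ctrl_peaks), " lenient peaks (p <= ",
          config$control_p, ")")
    }
    for (s in c("endogenous", "overexpressed")) {
      models[[s]] <- fit_background(cov[[s]], genome,
                                    window_size = config$window_size,
                                    gc_bin_width = config$gc_bin_width)
      pk <- call_peaks(cov[[s]], models[[s]], genome,
                       p_threshold = config$p_threshold,
                       merge_distance = config$merge_distance, sample = s)
      if (!is.null(ctrl_peaks)) pk <- subtract_control(pk, ctrl_peaks)
      peaks[[s]] <- pk
      write_bed(pk, file.path(out_dir, paste0("peaks_", s, ".bed")))
      fdr <- fdr_curve(cov[[s]], models[[s]], genome)
      write_tsv(as.data.frame(fdr),
                file.path(out_dir, paste0("fdr_", s, ".tsv")))
      say("  ", s, ": ", n_peaks(pk), " peaks (p <= ", config$p_threshold,
          ")")
    }
    result$control_peaks <- ctrl_peaks
  })
  result$models <- models
  result$peaks <- peaks

  stage("concordance", {
    bw <- min(config$rank_bin_width,
              n_peaks(peaks$endogenous), n_peaks(peaks$overexpressed))
    grid <- overlap_grid(peaks$endogenous, peaks$overexpressed,
                         bin_width = bw)
    write_tsv(data.frame(cutoff = grid$cutoffs, grid$fraction,
                         check.names = FALSE),
              file.path(out_dir, "overlap_grid.tsv"))
    mh <- matched_heights(peaks$endogenous, peaks$overexpressed,
                          cov$endogenous, cov$overexpressed)
    r <- asinh_pearson(mh$height1, mh$height2)
    say("  full-prefix overlap: ",
        round(grid$fraction[nrow(grid$fraction), ncol(grid$fraction)], 3),
        "; asinh-Pearson height correlation: ", round(r, 3))
    result$overlap_grid <- grid
    result$asinh_pearson <- r
  })

  stage("ebox_analysis", {
    ctrl_gr <- if (!is.null(result$control_peaks))
      result$control_peaks$peaks else NULL
    sites <- scan_eboxes(genome, exclude = ctrl_gr,
                         exclude_chroms = config$exclude_chroms)
    ranked <- list()
    for (s in c("endogenous", "overexpressed")) {
      ranked[[s]] <- rank_eboxes(sites, cov[[s]], models[[s]], genome)
      tab <- variant_distribution_by_bin(ranked[[s]])
      write_tsv(data.frame(bin = rownames(tab), unclass(tab),
                           check.names = FALSE),
                file.path(out_dir, paste0("ebox_bins_", s, ".tsv")))
    }
    ccdf <- coverage_ccdf(sites, proc[c("endogenous", "overexpressed")],
                          genome, seed = config$seed)
    result$ebox_sites <- sites
    result$ebox_ranked <- ranked
    result$ebox_ccdf <- ccdf
    if (!is.null(accessibility)) {
      result$accessibility_ccdf <- accessibility_ccdf(
        sites, accessibility, proc[c("endogenous", "overexpressed")],
        genome, seed = config$seed)
    }
    say("  ", length(sites), " E-boxes scanned")
  })

  stage("motif_analysis", {
    motifs <- list()
    for (s in c("endogenous", "overexpressed")) {
      fgset <- make_foreground(peaks[[s]], genome,
                               flank = config$motif_flank,
                               max_peaks = 2000L)
      bgset <- sample_background(genome, fgset, seed = config$seed)
      motifs[[s]] <- discover_motifs(fgset, bgset, k = 6L, n_motifs = 3L)
      write_tsv(motif_table(motifs[[s]]),
                file.path(out_dir, paste0("motifs_", s, ".tsv")))
      if (length(motifs[[s]]))
        write_meme(lapply(motifs[[s]], `[[`, "pwm"),
                   file.path(out_dir, paste0("motifs_", s, ".meme")))
      say("  ", s, ": ", length(motifs[[s]]), " motif(s)")
      if (length(motifs[[s]])) {
        bw <- min(config$rank_bin_width, n_peaks(peaks[[s]]))
        tab <- avg_pwm_by_rank(peaks[[s]], motifs[[s]][[1]]$pwm, genome,
                               bin_width = bw)
        write_tsv(tab, file.path(out_dir, paste0("pwm_by_rank_", s, ".tsv")))
      }
    }
    result$motifs <- motifs
  })

  say("pipeline complete")
  invisible(result)
}
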