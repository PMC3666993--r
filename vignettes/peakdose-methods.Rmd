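---
title: "Models and methods behind peakdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peakdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

peakdose compares the genome-wide binding profiles of a transcription
factor assayed by ChIP-seq at two protein doses — typically an endogenous
sample and an overexpressed one. This vignette explains the statistical
models the package implements, the parameters that matter, what the
synthetic-data generator emulates, and the numerical and design choices
that shaped the implementation. Nothing here states an empirical result
that the package's tests or `scripts/acceptance.R` do not themselves
compute.

## The analysis in one paragraph

Mapped single-end reads (BED intervals) are deduplicated, extended in
sequencing orientation to one fragment length, and piled into per-base
coverage. Background coverage is modelled as a negative binomial whose
parameters depend on local GC content; peak calling thresholds depth
against the NB upper tail, merges nearby runs, and assigns each peak a
summit p-value. A pooled control sample, peak-called at a lenient
threshold, removes recurrent artifact regions. Two samples are compared
non-parametrically by the fraction of the top-*x* peaks of one that
overlap the top-*y* peaks of the other over a grid of rank cutoffs, by the
Pearson correlation of asinh-transformed matched-locus heights, and by
height-ratio quantiles after sub-sampling both read sets to equal size.
Genome-wide E-boxes (CANNTG) are ranked by coverage significance to give
variant-preference-by-rank tables and coverage CCDFs, optionally
stratified by chromatin-accessibility scores. Finally, a discriminative
motif search with ZOOPS EM refinement recovers the binding motif and its
enrichment statistics.

## Read processing

Duplicate reads are collapsed on the full (chromosome, start, end,
strand) key; with fixed-length reads this is equivalent to collapsing on
the 5' position per strand, and it is the standard guard against PCR
amplification artifacts. Each read is then extended 3'-ward to
`extension_length` (default 200 bases, matching the fragment-size
selection typical of single-end ChIP-seq), clipped at chromosome bounds
so that read-mass accounting stays exact. Per-base depth is the number of
extended reads covering a base. Cross-sample comparisons that depend on
absolute depth (height ratios, E-box CCDFs, matched-height correlation)
first draw equal-sized read subsets from both samples, uniformly without
replacement under a fixed seed.

## The GC-conditioned negative-binomial background

### Why window size equals extension length

An extended read covers the interval `[anchor, anchor + L)`, so the depth
at a base equals the number of anchors in the trailing `L`-base span.
Windowed counts of anchors in non-overlapping `L`-base tiles therefore
have the same scale — and, under a locally homogeneous background, the
same marginal law — as per-base depth. The model is fitted to windowed
anchor counts and its tail probabilities are applied to depths, so using
`window_size = extension_length` (200 by default) keeps the two on one
scale. With a substantially larger window the fitted mean would exceed
the typical depth by the ratio of the sizes and every p-value would be
miscalibrated.

### Fitting: truncated maximum likelihood under a robust ceiling

Each window is assigned a GC bin (bin width 0.05; N bases are excluded
from the GC fraction; windows that are mostly non-mappable are dropped).
Within a bin, most windows are background but an unknown minority carry
signal. The fitter:

1. computes a robust ceiling `median + 3 * max(2 * (q50 - q25), 1)`.
   The spread estimate uses only the lower half of the count
   distribution, which bound windows — all in the upper tail — cannot
   move;
2. maximizes the negative-binomial likelihood *conditional on counts not
   exceeding the ceiling* (truncated ML). The conditioning makes the
   estimate unbiased on pure background regardless of how aggressive the
   ceiling is, which is what allows the ceiling to sit low enough to
   exclude bound windows;
3. tightens the ceiling to the `mask_alpha = 1e-4` upper tail of the
   fitted law when that is lower, and refits (up to `max_rounds`).

Underdispersed bins fall back to a Poisson law (`size = Inf`), and bins
with fewer than `min_windows` usable windows inherit the nearest fitted
bin. Simpler schemes were tried and rejected: fixed-fraction trimming of
a discrete NB biases the dispersion far beyond usable tolerances (for a
mean-2, size-2 background, trimming the top 1% inflates the fitted size
by tens of percent), and moment fits with model-based masking alone
diverge when signal is dense, because an NB with a small size parameter
can "explain" signal windows as dispersion so the masking ceiling never
comes down.

Windows that truly contain weak signal below the ceiling remain in the
fit; at high site density this residual contamination slightly inflates
the background and is an irreducible limit of window-level background
estimation rather than of this particular estimator.

### P-values, peaks, and the empirical FDR curve

`nb_tail_pvalue` returns the exact upper-tail mass `P(X >= observed)` of
the bin's fitted law. Peak calling converts the p-value threshold into a
per-bin integer depth threshold (the smallest depth whose tail mass does
not exceed the threshold), takes maximal runs of qualifying bases, merges
runs separated by fewer than `merge_distance` bases (one fragment length;
fragment-scale merging is standard practice), and reports each region's
summit, height, and summit p-value, ranked by ascending p-value with ties
broken by descending height then coordinate. Control peaks called from
pooled control reads at p <= 1e-3 remove overlapping sample peaks.

The FDR curve compares, per cutoff, the observed fraction of (usable)
genome bases reaching the depth threshold with the model-expected
fraction — the attainable tail mass at the discrete threshold averaged
over GC bins. The ratio expected/observed, capped at 1, is reported as
the empirical FDR; cutoffs with no observed coverage are undefined (NA)
rather than zero. Because counts are discrete, the attainable tail mass
at a threshold can sit well below the nominal cutoff; using the
attainable mass in the numerator keeps the ratio honest. On a finite
genome the curve is only informative down to cutoffs whose expected
number of exceedance events — events cluster over roughly one extension
length — is large enough to measure; on a 30 Mb null genome that is
about p = 1e-3 to 1e-4, and deeper grid points are reported as undefined
when nothing is observed.

## Rank-cutoff concordance

Peaks of two samples are compared by the fraction of the top-*x* peaks of
one sample overlapping (by at least one base; a summit-distance predicate
was considered and rejected because peak bodies, not summits, are what
replicate) any of the top-*y* peaks of the other, normalized by the
smaller of the two cutoffs so the fraction stays in [0, 1]. The grid
steps in multiples of `rank_bin_width` (5,000 for genome-scale data;
desk-scale fixtures use 500). For cells below the diagonal the overlap is
counted over the smaller list, keeping the fraction bounded. Matched
heights for the asinh-Pearson correlation are read from each sample's
coverage at the union of both samples' peak loci, so a locus missing from
one peak list contributes that sample's actual local depth rather than a
structural zero; asinh is used because it is log-like for large heights
but defined at zero.

## E-box analyses

CANNTG is its own reverse complement as a pattern class, so a
forward-strand scan enumerates every site exactly once. Variants are
canonicalized by taking the lexicographically smaller of the internal
dinucleotide and its reverse complement (CACCTG and CAGGTG are one
class). Site coverage is the maximum depth over the hexamer — the same
"height" semantics as peaks — and site p-values reuse the peak-calling
background model of the same sample. Ranked sites are binned (top 1K,
then to 10K, then to 100K, and so on until all sites are included) and
per-bin variant proportions are tabulated next to the genome-wide
background distribution.

Consensus-site CCDFs (the proportion of sites with coverage above each
threshold on a log2-spaced grid) are computed after equal-count read
sub-sampling, restricted to sites whose ±200-base window is uniquely
mappable; in real mode mappability is carried by FASTA soft-masking, in
synthetic mode by the generator's mask. Accessibility stratification
joins per-E-box scores by position and classes them low (0,1], moderate
(1,2], high (2,∞) — half-open on the left, so a score of exactly 1 is
low and exactly 2 is moderate. Sites without a score are excluded with a
logged count.

## Discriminative motif discovery and EM refinement

Foreground windows are peak summits ±50 bases; background windows are
random genomic windows matched to each foreground window's GC within
0.02 and to its log10 distance-to-TSS bin (10 bins), never overlapping a
foreground window. If a window's quota cannot be filled, the GC tolerance
is relaxed stepwise (finally the TSS constraint) with a warning, so the
procedure always terminates.

Discovery enumerates all exact words of length *k*, scores each by a
two-proportion z-statistic on per-sequence presence (either strand),
then greedily generalizes the best word one position at a time over
{R, Y, S, W, N} while |z| improves. Exhausting the full degenerate
alphabet at once would mean 9^k words; the greedy path reaches the same
family of degenerate words at a feasible cost. Accepted motifs are masked
out and the search repeats. The z-statistic is a documented, testable
discriminative score with the conventional sign convention (positive =
enriched in foreground); a regression-based score would serve the same
role but has more free choices to pin down.

`em_refine` fits a ZOOPS (zero-or-one occurrence per sequence) mixture:
each sequence either has no occurrence or one occurrence at some offset
on either strand. The E-step computes the exact posterior over
(no-occurrence, offset × strand); the M-step re-estimates PWM columns
with a Dirichlet pseudocount (0.25 per base) and the occurrence prior.
With a pseudocount the quantity EM provably never decreases is the
penalized objective (log-likelihood plus the Dirichlet log-prior), so
that is the monotonicity invariant the package records and tests; the
raw data log-likelihood is recorded alongside. Convergence is declared
when the largest PWM entry changes by less than `tol = 1e-4` (default
`max_iter = 100`). A seed word with no match in the foreground returns
the seed-derived PWM flagged `degenerate`, per the interface contract.

PWM scores are best-placement log2 odds against the background base
composition, maximized over offsets and strands; placements containing
non-ACGT bases are skipped, and a window with no valid placement scores
NA. The average-PWM-by-rank table takes, per peak, the best-scoring
E-box inside the peak (peaks with no E-box contribute a floor score,
default −20, clearly below any genuine match) and averages within rank
bins.

## The synthetic-data generator

The generator builds the study conditions the analysis assumes, not a
general genome simulator. Its defaults are the standard fixture used
throughout the tests:

* **Genome**: 3 chromosomes × 2 Mb, each in three equal segments with GC
  0.375 / 0.475 / 0.575 — enough GC spread to populate several bins of
  the background model. Thirty 2-kb tracts are duplicated from a donor
  segment and marked non-mappable (donor included), emulating repeats;
  300 TSS positions support distance-matched background sampling.
* **Background reads**: a Gamma-Poisson process. Each 200-base window's
  expected anchor count is `0.5 + 3 * gc` (at the window's GC-bin
  midpoint) with a Gamma multiplier of shape 2 shared across 2-kb
  blocks. Windowed counts are then marginally negative binomial with the
  configured mean and size, while interior per-base depth is Poisson at
  the block rate — hence also marginally NB — so background-parameter
  recovery and depth calibration are simultaneously well-posed.
  Independent per-window NB draws would fail the second property: depth
  spans straddling window boundaries would be thinned sums with roughly
  half the overdispersion. The coverage level emulates the regime where
  peak-calling depth cutoffs are tens of reads (a p = 1e-3 cutoff of
  ~8 reads and a 1e-10 cutoff of ~20 for the endogenous-scale sample).
* **Sites**: 5,000 positions on mappable sequence, at least 10 bases
  apart. Affinities are log-normal (sdlog 1.5); each CAGCTG-class site
  carries a latent log-normal accessibility score thresholded at 1 and 2
  into low/moderate/high classes multiplying occupancy by 0.3/1/3. The
  endogenous sample allocates 350,000 foreground reads to sites by a
  multinomial on affinity × accessibility; the overexpressed sample
  scales that mass by `dose_factor = 4`. The foreground mass is chosen
  so the default p = 1e-10 depth cutoff falls inside the effective
  affinity distribution: that is the regime the rank-concordance method
  targets, where the dose moves the callable set rather than calling
  essentially all sites in both samples.
* **Read geometry**: reads are 36 bases, placed strand-split around the
  site (forward reads 5', reverse reads 3') at offsets of 10–90% of the
  fragment length, so extension to 200 bases always covers the site.
* **Planted sequence**: each site carries an 8-mer of the form
  R R C A G S T G — consensus flanks and a preferred core (CAGCTG or
  CAGGTG, reverse-complement-equivalent to CACCTG) — with the
  probability of the preferred core (0.3 + 0.65q) and of consensus
  flanks (0.4 + 0.55q) increasing in the site's effective-affinity
  quantile q. Strong sites therefore look like consensus sites and weak
  sites degrade, which is what makes variant-by-bin enrichment and the
  PWM-score-versus-rank decay testable.
* **Control**: background plus 20 artifact spikes of ~150 reads at fixed
  loci; the generative model for artifacts is deliberately minimal
  (shared high spikes), since their real-data etiology is unknown.

What the generator does *not* emulate: sequencing errors and base
qualities, PCR duplication beyond what dense placement produces
naturally, fragment-length variability, copy-number variation, and any
cell-type difference between the two samples other than the dose factor.
Consequently, passing tests demonstrate that the pipeline's statistics
behave as designed under their own assumptions — calibrated null,
recoverable parameters, rank concordance driven by shared sites — not
that those assumptions hold for any particular real data set.

## Problem sizes and seeds

Module-level tests run a 1/10-scale fixture (2 × 300 kb, 500 sites);
end-to-end property checks use the full default fixture (3 × 2 Mb,
5,000 sites), a 3 × 10 Mb background-only genome for null calibration,
and a 3 × 2 Mb high-coverage background (mean `8 + 24 * gc`, size 5) for
parameter recovery — the high-coverage variant is used there because the
sampling error of the estimator at the default low coverage would be of
the same order as the tolerance being checked, making the check
uninformative about bias. The planted-motif experiment uses 500
foreground and 500 background windows of width 101. All randomized steps
take explicit integer seeds, and every simulation is deterministic given
its configuration seed.

## Known limitations

* Window-level background estimation cannot separate weak bound windows
  from background; at high site density the background mean is slightly
  inflated and the dispersion deflated, which makes peak calling mildly
  conservative for both samples.
* The empirical FDR curve is resolution-limited by genome size at
  stringent cutoffs (undefined where nothing is observed).
* The two-proportion z-score ranks motifs by marginal discrimination;
  correlated motifs are handled greedily by masking, not jointly.
* Degenerate-word search is greedy; a word reachable only through two
  simultaneous generalizations can be missed.
* Peak heights saturate when a site's read mass approaches the number of
  distinct placement positions, compressing dose ratios at very strong
  sites (a deduplication effect real data share).

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates all
fixtures from scratch and recomputes the quantities discussed here —
the NB tail oracle error, background recovery errors, the null FDR, the
two-sample overlap fraction and peak-count ratio, the asinh-Pearson
height correlation, E-box variant enrichment, the accessibility CCDF
gap, the PWM-by-rank decay, and planted-motif recovery — writing them as
JSON.
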