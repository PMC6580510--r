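---
title: "Methods: DHS calling, metagene profiling and dual-order bivalent analysis"
author: "coldchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DHS calling, metagene profiling and dual-order bivalent analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldchrom)
```

## What this package computes

`coldchrom` implements an analysis of cold-stress chromatin dynamics built
around four computations:

1. **DHS calling.** DNase I hypersensitive sites are called from single-bp
   cut-site tracks by Gaussian kernel density estimation with an empirical,
   Monte-Carlo-calibrated FDR threshold; DHSs are retained only when the two
   biological replicates of a sample overlap by at least 1 bp (consensus),
   and a consensus DHS is *condition-specific* when it shares no single base
   pair with any DHS of the other condition.
2. **Feature assignment.** Each DHS is assigned to a genomic feature by its
   *summit* — the single base pair with the most cuts — regardless of where
   the rest of the interval falls.
3. **Metagene profiling.** Signal (DNase cuts, or ChIP fragment midpoints)
   is summarized per gene in 100 body bins from TSS to TTS plus 100 bins
   over each 1 kb flank, normalized to events per bp per million mapped
   reads.
4. **Bivalent calling.** Sequential ChIP (re-ChIP) signal over gene bodies
   is normalized to the matching no-antibody control; a gene is called
   bivalent (H3K4me3 + H3K27me3 on the same nucleosomes) only when its
   score increases upon cold in *both* antibody orders, K4-K27 and K27-K4 —
   the dual-order requirement that excludes single-antibody carry-over.

A synthetic-data generator emulates the structure of the study the analysis
is designed for (two replicates for each of room-temperature tubers, cold
tubers and leaves; nine ChIP channels; an expression table with two DE
caller outputs) with planted ground truth, so every stage is testable
without downloads.

## The DHS caller

For a chromosome with cut positions $x_1 \dots x_n$ the per-bp density is

$$ f(p) = \sum_{i=1}^{n} \phi\!\left(\frac{p - x_i}{h}\right)\frac{1}{h}, $$

a Gaussian kernel sum with bandwidth $h$ (default 300 bp, exposed in
`caller_params()`). It is evaluated at every base pair by FFT convolution of
the per-bp count vector with a kernel truncated at ±7 standard deviations;
tests verify agreement with direct summation to below $10^{-9}$.

The calling threshold is calibrated empirically rather than parametrically:
`n_null` (default 20) pseudo-libraries of the same size are placed uniformly
on the effective genome, their densities pooled, and the threshold is the
smallest density $t$ for which

$$ \frac{\mathbb{E}[\text{null bases} \ge t]}{\text{observed bases} \ge t} \le \text{FDR} $$

with FDR 0.05 by default. The ratio is computed on a 4096-bin histogram of
density values, which keeps 20 genome-scale simulations in constant memory
and makes the threshold deterministic per seed. When no density level
satisfies the criterion — an observed track indistinguishable from noise —
the threshold is `Inf` and no DHSs are emitted. On pure-null tracks this
construction is conservative: the fraction of the genome called is far
below the nominal FDR, because an excess of observed high-density bases
over the null expectation is exactly what a null track does not have.

Maximal runs of bases at or above the threshold become DHSs after optional
gap merging (`merge_gap`, default 0) and a minimum length filter
(`min_length`, default 50 bp). The summit is the leftmost base with the
maximal raw cut count in the run. Note the two-scale design: the *interval*
comes from the smoothed density, the *summit* from raw counts. A raw-count
summit on a smooth hotspot is intrinsically jittery — neighbouring bases
have nearly equal expected counts — so summit accuracy is assessed as a
median over hotspots (about 20 bp at five-fold enrichment in the package's
recovery checks), not as a per-hotspot guarantee.

Consensus intervals take the union span of the replicate-1 DHS and its
overlapping replicate-2 partners; the summit is inherited from the
replicate with the larger summit count (replicate 1 on ties). An
alternative that keeps replicate-1 coordinates is a one-line change in
`consensus_dhs()`; the union was chosen so that no replicate-supported
base is lost.

## Feature assignment and its precedence

Positions are classified as exon, intron, 1 kb upstream of a TSS, 1 kb
downstream of a TTS, or intergenic (more than 1 kb from every TSS and TTS),
with windows oriented by strand. When windows of different genes overlap,
precedence is exon > intron > upstream > downstream > intergenic — genic
evidence wins, consistent with the analysis's focus on genic DHSs. Within
one precedence rank the gene with the nearest TSS is chosen, then the
lexicographically smallest gene id. The precedence and tie-breaks are
documented choices: annotated feature hierarchies do not define them, and
any fixed rule keeps the classification total and deterministic. A refined
category set (TSS200, TTS200, 1–5 kb intergenic) is available via
`refined = TRUE`. Each gene has exactly one transcript model; isoforms are
out of scope.

Genes shorter than the bin count (100 bp with defaults) cannot be divided
into non-empty bins and are excluded from metagene analyses with a warning.

## Normalization

All signal is scaled as `count / length / (library_size / 1e6)` — events
per bp per million mapped reads (`normalize_signal()`). ChIP levels are
additionally divided by the same quantity in the input channel
(`chip_signal()`), and bivalent levels by the matching no-antibody control
(`bivalent_score()`). Denominators are floored at $\varepsilon = 0.01$
normalized units, and log-ratios add the same $\varepsilon$ as
pseudo-signal; this keeps silenced-gene and zero-coverage ratios finite
while being one to two orders of magnitude below typical genic signal.
Events on a bin boundary belong to the left (half-open) bin; fragments are
counted by their midpoint, cuts by the cut base itself.

Because every channel is normalized to its own depth, all calls are
invariant under uniform depth rescaling of any channel (verified by test).

## The bivalent decision rule

`call_bivalent()` flags an active gene when
`score_cold > min_fold * score_RT` in both antibody orders, with
`min_fold = 1` — a strict inequality with no minimum effect size, mirroring
the stated selection of the study it implements; a larger `min_fold` is
available for stringency. Both orders must agree: carry-over from the first
antibody inflates K4-K27 and K4-noAb alike and single-order increases are
therefore not sufficient. With the synthetic generator's composition (true
bivalent signal claims a fraction of sequential-ChIP depth only in cold),
non-bivalent genes drift slightly *below* their RT score upon cold, which
is why the strict rule attains high precision; on real data with weaker
composition effects `min_fold` is the stringency dial.

## Statistical machinery

* `proportion_ztest()` — pooled-variance two-proportion z with two-tailed
  normal p and no continuity correction (pooled vs unpooled variance is not
  derivable from the source analysis; pooled is the documented choice).
  Calibration is verified by a KS test of null p-values at group size 2000,
  where binomial discreteness no longer dominates.
* `wilcoxon_rank_sum()` — exact enumeration over all $\binom{n}{n_a}$
  group assignments (valid under ties, using midranks) when $n \le 12$;
  tie-corrected normal approximation with continuity correction otherwise.
  The two branches agree to ~0.01 in the median at $n = 6 + 6$; exact
  two-sided p-values at that size are discrete with jumps up to ~0.06, so
  pointwise agreement beyond that is not achievable.
* `sensitivity_change()` reports both the paired signed-rank test across
  genes and the unpaired rank-sum between the per-gene signal sets; which
  of the two the original analysis used is not stated, so both are given.
* `window_density_correlation()` — Pearson correlation of event counts in
  non-overlapping windows (100 bp for replicate coverage; larger windows
  for density-vs-density comparisons, where the window size is a free
  choice).

## The synthetic study and what it does (not) show

`sim_config()` defaults define the study conditions once:

* genome: 2 chromosomes × 2 Mb; 400 genes of 1.5–4 kb in jittered slots
  with ≥ 2 kb spacing (so length-matched intergenic controls always exist);
  1–4 exons per gene.
* expression classes up/down/constitutive/silenced at 20/20/40/20%;
  active = non-silenced, FPKM > 1 in both tuber conditions; planted fold
  changes ≥ 1.6; two DE tables agreeing exactly on the planted DEGs with
  disjoint caller-specific false positives.
* DNase libraries of 2e5 cuts: half uniform background, half in Gaussian
  hotspots (sd 75 bp) at promoters (TSS−100 in transcription orientation,
  where observed sensitivity peaks ~200 bp upstream of TSSs), scaled by
  expression quartile, with ~8% per-condition promoter dropout so both
  temperatures have specific DHSs. In cold only, genes flagged
  `genic_dhs_cold_only` (all bivalent-planted genes at 1.8× weight plus
  55% of the other active genes) gain gene-body hotspots centred on fixed
  internal nucleosomes. Gene length 1.5–4 kb keeps those body hotspots
  separable from the promoter DHS under the 300 bp kernel.
* ChIP channels of 2e5 fragments (~150 bp) on a fixed 180 bp nucleosome
  grid shared by all channels: H3K4me3/H4ac on the 5' half of active gene
  bodies, H3K27me3 on silenced bodies, and in cold both marks plus H3K4me1
  across bivalent-planted bodies (30% of active genes). Sequential
  channels emit true signal only from dual-marked nucleosomes (25% of
  depth when present); no-antibody controls emit from the first antibody's
  nucleosomes at `carryover_rate` (default 0.1) plus uniform background;
  input is uniform over the grid.
* depths are sized so the full six-library calling run finishes in a few
  minutes on one CPU; recovery checks use a 1 Mb chromosome with 2e5 cuts.

Sub-seeds per (stage, condition, replicate, channel) derive from the master
seed by a small string hash, so replicates are independent yet the whole
study is reproducible from one integer.

The generator emulates *structure*, not the organism: per-condition hotspot
intensity distributions are free parameters (chosen as above, not fitted to
any deposited data), background is homogeneous Poisson with no mappability
or GC structure, nucleosomes are perfectly phased, and fragment-level
artifacts (duplicates, chimeras) do not exist. Passing recovery tests
therefore demonstrates that the *operations* are correct and calibrated
under their stated model — not that real tissue would yield the published
counts, which depend on genome scale and library properties the desk-scale
simulation deliberately does not reproduce. Reported genome-scale
percentages are instead checked as ratio arithmetic on the published count
pairs themselves.

## Numerical choices and degenerate inputs

* KDE kernel truncated at ±7 sd (truncation error < 1e−12 per cut); FFT
  length padded to a 2-3-5-smooth number; kernel FFT memoised.
* Density histogram for thresholding: 4096 bins on [0, observed max];
  values above the top edge clamp into the last bin (they can only tighten
  the threshold).
* Summit ties: leftmost. Ranking ties in `top_dhs_regions()`: summit count,
  then coordinate.
* Quartile ties: a tie group straddling a boundary goes whole to the lower
  quartile.
* Empty inputs: empty tracks yield empty DHS sets and zero matrices; an
  all-tied rank-sum returns p = 1; a degenerate pooled proportion (0 or 1)
  returns z = 0, p = 1; zero library sizes are errors, not silent zeros.

## Known limitations

* One transcript model per gene; nested or overlapping genes are resolved
  only by the stated precedence.
* No Tn5/ATAC offset handling, no mappability masking, no spike-in
  normalization.
* The Monte-Carlo null assumes uniform placement over the effective genome;
  real accessibility backgrounds are inhomogeneous, which makes the
  empirical threshold conservative on depleted regions.
* `consensus_dhs()` is asymmetric in its bookkeeping (one record per
  replicate-1 DHS); counts quoted per sample follow replicate 1.

## A minimal run

```{r, eval = FALSE}
cfg <- run_config(
  sim = sim_config(n_chroms = 1, chrom_length = 3e5, n_genes = 40,
                   dnase_depth = 5e4, chip_depth = 5e4, seed = 5),
  caller = caller_params(n_null = 8, seed = 5),
  out_dir = "results/minimal")
res <- run_pipeline(cfg)
res$stats
```

The numbered scripts under `analysis/` run the full synthetic study
(simulate → call → classify → profile → bivalent → report) and write their
tables under `results/`.
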