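# coldchrom

Chromatin accessibility and bivalent histone-mark analysis for cold-stress
epigenomics in R.

Cold storage reshapes the chromatin of plant tissue: open-chromatin regions
(DNase I hypersensitive sites, DHSs) appear inside gene bodies, active genes
become more accessible, and sequential ChIP (re-ChIP) shows the active mark
H3K4me3 and the repressive mark H3K27me3 arriving on the *same* nucleosomes
of a third of the active genes. `coldchrom` is for analysts who want to run
that style of analysis — DNase-seq hotspot calling, condition comparison,
metagene profiling, and dual-order bivalent calling — as a tested, seeded R
pipeline, either on their own BED/BEDPE/GFF3/TSV inputs or on a built-in
synthetic study with planted ground truth.

## The methods at its core

**KDE DHS calling with empirical FDR.** Per-bp cut density
`f(p) = Σᵢ N(p; xᵢ, h)` with bandwidth `h = 300` bp, computed by FFT
convolution. The threshold is calibrated against `n_null = 20` uniform
placements of the same library on the effective genome: the smallest `t`
with `E[null bases ≥ t] / (observed bases ≥ t) ≤ FDR` (default 0.05). DHSs
are maximal runs above `t` (≥ 50 bp); the summit is the leftmost base with
the maximal raw cut count. Consensus keeps DHSs overlapping ≥ 1 bp between
replicates; a DHS is condition-specific when it shares no base with the
other condition's set.

**Summit-based feature assignment.** A DHS belongs to the feature containing
its summit (exon > intron > 1 kb upstream > 1 kb downstream > intergenic,
strand-aware).

**Metagene profiles.** Genes aligned TSS→TTS in 100 bins plus 100 bins per
1 kb flank; signal is events (cuts, or fragment midpoints) per bp per
million mapped reads; ChIP levels divide additionally by input.

**Dual-order bivalent calling.** Gene-body re-ChIP signal normalized to the
matching no-antibody control (K4-K27 / K4-noAb and K27-K4 / K27-noAb); a
gene is bivalent only if the score rises upon cold in *both* antibody
orders — the control structure that excludes first-antibody carry-over.

Supporting statistics: pooled two-proportion z test (two-tailed), Wilcoxon
rank-sum with exact enumeration at n ≤ 12 (ties included), windowed Pearson
density correlation.

## Worked example

A small synthetic end-to-end run (one 300 kb chromosome, 40 genes):

```r
library(coldchrom)
cfg <- run_config(
  sim = sim_config(n_chroms = 1, chrom_length = 3e5, n_genes = 40,
                   dnase_depth = 5e4, chip_depth = 5e4, seed = 5),
  caller = caller_params(n_null = 8, seed = 5),
  out_dir = "results/minimal")
res <- run_pipeline(cfg)
str(res$stats)
#> List of 12
#>  $ n_consensus                   : Named int [1:2] 30 49
#>   ..- attr(*, "names")= chr [1:2] "RT" "cold"
#>  $ n_specific                    : Named int [1:2] 20 1
#>   ..- attr(*, "names")= chr [1:2] "cold" "RT"
#>  $ n_active                      : int 34
#>  $ n_silenced                    : int 6
#>  $ n_up                          : int 4
#>  $ n_down                        : int 9
#>  $ n_constitutive                : int 21
#>  $ n_bivalent                    : int 7
#>  $ pct_bivalent_of_active        : num 20.6
#>  $ median_log2_sensitivity_change: num 0.74
#>  $ wilcoxon_p_paired             : num 9.04e-05
#>  $ replicate_coverage_r          : num 0.994
```

Reading the output: the cold condition yields more consensus DHSs (49 vs
30) and almost all condition-specific DHSs (20 vs 1) because the generator
plants cold-only gene-body hotspots; active-gene bodies get more accessible
upon cold (median log2 ratio 0.74, paired Wilcoxon p ≈ 9e-5); 7 of 34
active genes are called bivalent by the dual-order rule; replicate coverage
correlates at r ≈ 0.99. The `out_dir` receives the annotation (GFF3), DHS
BEDs and summits, metagene TSVs, the bivalent call table and a statistics
JSON with a run manifest.

The full-scale synthetic study (2 × 2 Mb, 400 genes, three conditions) is
driven by the numbered scripts:

```sh
Rscript analysis/01_simulate.R    # genome, truth labels, expression, DE tables
Rscript analysis/02_call_dhs.R    # per-replicate calls, consensus, specific sets
Rscript analysis/03_classify.R    # feature distributions, DEG association, z tests
Rscript analysis/04_metagene.R    # quartile metagene profiles, sensitivity change
Rscript analysis/05_bivalent.R    # dual-order bivalent calls vs planted truth
Rscript analysis/06_report.R      # summary JSON
```

each printing what it found (e.g. stage 5: `bivalent: 106/327 active genes
called (32%); planted 105; precision 0.991, recall 1.000`).

## Layout

```
R/                  package code (tracks, annotation model, DHS caller,
                    metagene, bivalent, statistics, I/O, pipeline)
analysis/           numbered drivers for the full synthetic study
tests/testthat/     unit, property and end-to-end acceptance tests
scripts/acceptance.R
vignettes/cold-chromatin-methods.Rmd   model, assumptions, design choices
```
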