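---
title: "Methods: co-occupancy, enhancer and signal analysis with glrscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy, enhancer and signal analysis with glrscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glrscope)
```

## Scope and model

glrscope implements the computational chain used to show that LSD1
inhibition activates GFI1-bound enhancers: co-occupancy classification of
transcription-factor peaks, active-enhancer calling from histone-mark
peaks, windowed signal quantification with condition fold changes,
peak-to-gene linking, and ranked gene-set enrichment. Sequencing-read
alignment and peak calling are out of scope — peaks (MACS2-style) and
coverage (bedGraph) are inputs.

All internal coordinates are 0-based half-open (BED convention); GTF and
MACS2 tables (1-based) are converted at the file boundary. Strand plays
no role in any distance or coincidence rule.

## Co-occupancy by apex distance

Two peaks are coincident when their apexes lie within a window `w`
(default **500 bp, boundary inclusive**: a 500 bp separation counts) on
the same chromosome. Coincidence percentages (`coincidence_summary()`)
count queries with *any* partner in range. The category partition
(`partition_categories()`) is stricter: it assigns every peak to exactly
one site. GFI1 peaks anchor all G-containing categories; LSD1 and RCOR1
partners are claimed **one-to-one, greedily by ascending apex distance**
(deterministic tie-breaks by coordinate), which prevents one LSD1 peak
from being counted at two adjacent GFI1 sites. Whether the original
analysis enforced one-to-one claiming, and which factor anchored triple
sites, is not stated in its description; anchoring on GFI1 with greedy
claiming is this package's documented choice, and triple sites require
only that LSD1 and RCOR1 each fall within the window of the GFI1 apex
(no mutual L–R constraint). Unclaimed LSD1/RCOR1 peaks then pair into LR
sites or remain singletons.

Strength stratification (`top_fraction()`) keeps the `ceil(f·n)`
strongest peaks by pileup, ties broken by coordinate. Reported
percentages are rounded **half-up** at the printed precision
(`percent_of()`), matching the convention of published percentage tables.

## Active intergenic enhancers

An active intergenic enhancer is an H3K9Ac peak that (i) overlaps an
H3K4Me2 peak by at least one base and (ii) lies at least 5 kb from any
annotated gene *locus* (not just the TSS — the stricter reading of
"distance from a gene"). "Coincident" histone peaks are interpreted as
interval overlap rather than apex distance because broad histone peaks
have unstable summits; an apex-distance mode is retained as a
configuration switch. The region is the union of the overlapping
intervals; its center is the H3K9Ac apex (acetylation marks the active
center); overlapping retained regions merge, keeping the strongest
H3K9Ac apex. LSD1 binding at an enhancer is flagged when an LSD1 apex
falls within the coincidence window of the center.

Location annotation (`annotate_location()`) classifies a peak by its apex
with precedence promoter > exonic > intronic > intergenic; the promoter
window is TSS ± 1 kb (inclusive), reused for the promoter-binding flag.

## Windowed RPKM and fold changes

Coverage tracks are per-base step functions with a library-size
normaliser. The estimated read count in a window is the depth integral
divided by the read length (tracks, not reads, are the input; this
contract makes closed-form oracles exact), and

```
RPKM = count × 1e9 / (window_length × total_mapped_reads)
```

Windows clip at chromosome ends and the clipped length enters the
denominator; a window clipped to nothing yields `NA`. The condition
summary at a site set is the **ratio of group means**,
`100·(mean_trt/mean_ctrl − 1)`, not the mean of per-site ratios — the
estimator that matches "mean signal increased by X%" phrasing; per-site
log2 fold changes carry a 0.5 RPKM pseudocount so zero-signal sites stay
finite. Meta-profiles and heatmap matrices share one per-site × per-bin
computation, so heatmap column means equal the meta-profile by
construction (defaults: flank 1 kb, 25 bp bins; 2.5 kb flanks for
promoter/enhancer comparisons).

## Expression integration

DE thresholds are inclusive at ±0.5 log2FC. The "expressed" flag is an
input column (optionally derived from a mean-expression floor): which
genes count as expressed is a property of the upstream RNA-seq
processing, not recoverable from summary tables. Sites link to the gene
with the nearest TSS (ties to the lexicographically smaller gene id, so
results are reproducible across platforms).

The enrichment score is the standard weighted Kolmogorov–Smirnov running
sum; at weight exponent 0 its magnitude equals the classical two-sample
KS statistic between hit and miss ranks (tested against `ks.test`, and
against fgsea at exponent 1). The null distribution uses **gene-set
permutation** — random sets of equal size drawn from the ranked genes —
because the input is a precomputed ranked list with no phenotype labels.
`NES = ES / mean(|null ES| of matching sign)`; the nominal p-value adds
one pseudo-observation; FDR across sets is Benjamini–Hochberg. A seed is
mandatory. Strength-stratified expression uses one-way ANOVA with Tukey
HSD (Fisher's LSD and pairwise Welch t-tests are available through
`group_compare()` for the comparisons that used them).

## The simulator and what it does (not) emulate

`simulate_dataset()` generates the full experiment with planted truth.
Defaults encode the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_gfi1_peaks` | 2000 | GFI1 anchor sites, all intergenic |
| `coincidence_lsd1` / `coincidence_rcor1` | 0.7 / 0.35 | planted partner fractions |
| `strength_coupling` | 6 | logistic slope of partner probability in pileup rank |
| `apex_jitter_sd`, `jitter_max` | 100, 400 bp | partner apex jitter, truncated |
| `enhancer_fc_acetyl` | 1.5 | treated/control acetylation effect at GLR sites |
| `de_effect`, `de_noise_sd` | 0.8, 0.2 | log2FC planted on genes nearest strong GLR sites |
| `de_pileup_threshold` | 35 | "strong" site cut (inclusive) |
| `background_depth` | 0.2 | per-base Poisson noise mean |
| `kernel_halfwidth` | 300 bp | triangular coverage kernel half-width |

Design choices worth knowing:

* **Jitter truncation at ±400 bp** keeps every planted partner inside the
  ±500 bp rule, separating classifier correctness from generator leakage;
  the margin is a test knob. Factor-only peaks sit > 1 kb from every GFI1
  apex, and anchor sites are ≥ 2 kb apart, so planted categories are
  unambiguous and the partition recovers them exactly.
* **Partner probability** is logistic in pileup rank with the intercept
  solved so the mean equals the planted fraction; slope 6 reproduces the
  observed pattern that the strongest peaks are almost always co-bound
  while preserving the overall fraction.
* **Coverage** is per-base Poisson background plus a triangular (tent)
  kernel of height equal to the pileup at each apex — chosen for its
  closed-form window integrals, which the tests use as oracles. The noise
  model is a modelling choice; nothing in the source analysis specifies
  one.
* **Depth-matched conditions.** Both conditions of a mark share one
  `total_mapped_reads` (taken from the control track). The fold-change
  estimator requires both tracks on the same normalisation basis; letting
  the planted signal gain inflate the treated library size would bias the
  recovered percent change downward by the gained fraction of total mass.
* **Expression** is log-normal baseline with Normal log2FC noise; target
  genes (nearest strong triple-occupied sites by the same nearest-TSS
  rule the pipeline uses) receive the planted effect.
* One master seed drives independent per-stage substreams, so each stage
  is reproducible in isolation.

What the simulator does **not** emulate: fragment-length and
strand-shift structure, input/IgG controls, copy-number and mappability
artifacts, promoter-bound peaks (all simulated factor sites are
intergenic), overdispersed biological replicate noise, and realistic
gene-density variation. Passing recovery tests therefore demonstrates
correctness of the analysis logic under a clean generative model, not
robustness to every artifact of real ChIP-seq.

## Numerical choices and degenerate inputs

Empty query sets, empty/full gene-set intersections, zero control means,
missing seeds and non-positive thresholds are errors, not silent
defaults. Missing narrowPeak summits (−1) fall back to the floored
interval midpoint. Ties are always broken deterministically (coordinate
order, or lexicographic gene id). Percent rounding is half-up.
Chromosomes absent from a track read as zero depth; chromosomes without
genes make nearest-gene queries an error by default and a warned `NA`
where the caller opts in.

## Problem sizes

The test suite and the acceptance script run the study-scale simulation —
five 6 Mb chromosomes, 800 genes, 2,000 GFI1 anchors (~7,800 peaks in
all), four coverage tracks, 1,000-permutation GSEA — in well under a
minute on one CPU; property tests use 100 random instances of up to 200
peaks against brute-force oracles, and permutation calibration uses 50
null simulations at 200 permutations each. These sizes were chosen so the
sampling-error bounds stated for each recovery test (binomial 3σ for
coincidence, ±5 percentage points for signal change, 3σ/√n for the DE
effect) are comfortably tighter than the planted effects.

## Known limitations

* Coincidence is purely apex-distance based; reciprocal-overlap modes are
  out of scope.
* The enhancer definition uses H3K9Ac/H3K4Me2 only (by design), with a
  single-base overlap criterion; a minimum-overlap fraction is not
  implemented.
* GSEA supports gene-set permutation only; phenotype permutation would
  need sample-level expression.
* RPKM is computed from depth integrals; fragment-count RPKM from BAMs is
  out of scope (tracks are the input).
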