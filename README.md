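# glrscope

Integrative ChIP-seq/RNA-seq analysis of GFI1–LSD1–RCOR1 co-occupancy and
the chromatin response to LSD1 inhibition.

## The problem

LSD1 (KDM1A) is a histone demethylase and a structural scaffold of the
CoREST corepressor complex (with RCOR1). In acute myeloid leukemia, the
transcription repressor GFI1 recruits LSD1/RCOR1 to enhancers; LSD1
inhibitors evict the complex from chromatin and activate those enhancers —
raising local histone acetylation and nearby gene expression — without
measurable accumulation of the H3K4 methylation that LSD1 nominally
demethylates. Demonstrating this genome-wide takes a chain of analyses
over called peaks, coverage tracks and expression tables:

1. **Peak co-occupancy by apex distance.** Two factors are coincident at a
   site when their peak summits ("apexes") lie within ±500 bp (inclusive).
   Sites are partitioned into Venn categories (GLR, GL, GR, G, LR, L, R)
   anchored on the GFI1 apex, with partners claimed one-to-one, greedily by
   ascending apex distance. Co-occupancy is also stratified by peak
   strength (MACS2 pileup): the strongest 5% of GFI1 peaks are almost
   always co-bound.
2. **Active intergenic enhancers.** Regions at least 5 kb from any
   annotated gene carrying coincident (overlapping) H3K9Ac and H3K4Me2
   peaks.
3. **Windowed RPKM signal.** For a coverage track with library size `N`
   and read length `L`, the signal over a window of `w` bp with depth
   integral `S` is

   `RPKM = (S / L) x 1e9 / (w x N)`

   Condition fold change at a site set is summarised as
   `100 x (mean_treated / mean_control − 1)` over per-site RPKM
   (center ± 1 kb), with per-site `log2((x_t + 0.5)/(x_c + 0.5))`.
   Meta-profiles and strength-ranked heatmap matrices use the same
   per-bin quantification.
4. **Expression integration.** DE genes thresholded at |log2FC| ≥ 0.5;
   peak-to-gene linking by nearest TSS; expression compared across
   site-strength strata (pileup ≥ 35 vs < 35 vs background; one-way ANOVA
   with Tukey HSD); and gene-set enrichment by the weighted
   Kolmogorov–Smirnov running sum

   `ES = extremum_i [ sum_{hits ≤ i} |r_j|^p / sum_hits |r_j|^p − (#misses ≤ i)/(N − N_h) ]`

   with gene-set permutation, `NES = ES / mean |ES_null, same sign|`, and
   Benjamini–Hochberg FDR across sets.

Because the original sequencing data are not available at desk scale, the
package ships a seeded simulator that generates the whole experiment with
planted ground truth — coupled co-binding fractions, a multiplicative
acetylation effect confined to triple-occupied (GLR) sites, and an
expression effect on genes nearest strong GLR sites — so every stage of
the pipeline is validated by parameter recovery.

## Worked example

```r
library(glrscope)
sim <- simulate_dataset(sim_config(seed = 1))   # ~10 s
report <- run_pipeline(sim)
report
```

prints (abridged):

```
glrscope run report
  peaks: GFI1=2000, LSD1=3428, RCOR1=1717, H3K9Ac=1323, H3K4Me2=1323
  1428 of 2000 peaks (all) coincident with LSD1 (window ±500 bp): 71.4%
  717 of 2000 peaks (all) coincident with RCOR1 (window ±500 bp): 35.9%
  100 of 100 peaks (top5%) coincident with LSD1 (window ±500 bp): 100%
  87 of 100 peaks (top5%) coincident with RCOR1 (window ±500 bp): 87%
  category sites: 5000 (GLR: 648)
  active intergenic enhancers: 1318 (79% LSD1-bound)
  H3K9Ac signal change at GLR sites (n=648): +47.4%
  H3K9Ac signal change at other sites (n=675): -0.0%
  DE genes at |log2FC| >= 0.5: 279 up, 1 down of 800 expressed
  GSEA GLR_linked_genes (n=440): ES=0.887 NES=2.28 p=0.000999
  parameter recovery (planted -> estimated):
    coincidence_lsd1: 0.7 -> 0.714
    acetyl_percent_change_glr: 50 -> 47.4
    de_effect: 0.8 -> 0.797
```

Reading: the simulator planted an LSD1 partner for 70% of GFI1 peaks and
the pipeline measures 71.4%; strength coupling makes the strongest 5%
fully co-bound; the planted 1.5× treated-condition acetylation effect at
GLR sites is recovered as +47.4% mean signal change (slightly attenuated
by Poisson background inside the ±1 kb windows) with no change at other
sites; and the genes linked to GLR sites are strongly enriched among
upregulated genes.

The numbered drivers under `analysis/` run the same stages as a file-based
workflow (`Rscript analysis/01_simulate.R` … `05_integrate.R`), writing
summary tables under `results/` and bulky intermediates under `scratch/`.

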