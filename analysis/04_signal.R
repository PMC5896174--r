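#!/usr/bin/env Rscript
# Stage 4 — normalized signal and condition fold changes.
#
# Quantifies H3K9Ac and H3K4Me2 RPKM (center ± 1 kb) at GLR versus other
# marked sites in both conditions, reports the percent change of mean
# signal, and writes the H3K9Ac meta-profile and the column means of the
# strength-ranked heatmap at GLR sites.

source("analysis/common.R")

sim <- get_sim()
assignments <- partition_categories(sim$peaks$GFI1, sim$peaks$LSD1,
                                    sim$peaks$RCOR1)
rep <- run_pipeline(sim)   # includes the per-mark fold-change table
print(rep$signal)
write_result(rep$signal, "signal_changes.tsv")

glr <- assignments[assignments$category == "GLR", ]
anchors <- data.frame(chrom = glr$chrom, pos = glr$apex)
for (cond in c("DMSO", "OG86")) {
  mp <- meta_profile(sim$tracks[[paste0("H3K9Ac.", cond)]], anchors,
                     flank = 1000, bin_width = 25)
  names(mp)[2] <- paste0("rpkm_", cond)
  if (cond == "DMSO") prof <- mp else prof[[names(mp)[2]]] <- mp[[2]]
}
cat(sprintf("H3K9Ac meta-profile at %d GLR sites: peak %.1f (DMSO) vs %.1f (OG86) RPKM\n",
            nrow(anchors), max(prof$rpkm_DMSO), max(prof$rpkm_OG86)))
write_result(prof, "h3k9ac_glr_metaprofile.tsv")

hm <- heatmap_matrix(sim$tracks[["H3K9Ac.DMSO"]],
                     sim$peaks$GFI1, flank = 1000, bin_width = 25)
stopifnot(nrow(hm) == nrow(sim$peaks$GFI1))
cat(sprintf("heatmap matrix: %d sites x %d bins, strongest first\n",
            nrow(hm), ncol(hm)))
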