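#!/usr/bin/env Rscript
# Stage 3 — active intergenic enhancers and genomic location annotation.
#
# Calls enhancers as H3K9Ac peaks overlapping an H3K4Me2 peak at least
# 5 kb from any gene locus, flags LSD1 binding at their centers, and
# annotates the genomic location class of every LSD1 peak.

source("analysis/common.R")

sim <- get_sim()

enh <- call_active_enhancers(sim$peaks$H3K9Ac, sim$peaks$H3K4Me2, sim$genes,
                             lsd1 = sim$peaks$LSD1)
n_bound <- sum(enh$lsd1_bound)
cat(sprintf("active intergenic enhancers: %d\n", nrow(enh)))
cat(sprintf("  LSD1-bound: %d (%s%%); unbound: %d (%s%%)\n",
            n_bound, percent_of(n_bound, nrow(enh)),
            nrow(enh) - n_bound,
            percent_of(nrow(enh) - n_bound, nrow(enh))))
write_result(data.frame(
  n_enhancers = nrow(enh),
  n_lsd1_bound = n_bound,
  pct_lsd1_bound = percent_of(n_bound, nrow(enh)),
  median_width = stats::median(enh$end - enh$start),
  min_gene_distance = min(enh$distance_to_gene)),
  "enhancer_summary.tsv")
# full table is bulky; keep it in scratch
dir.create("scratch", showWarnings = FALSE)
utils::write.table(enh, "scratch/enhancers_full.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ann <- annotate_location(sim$peaks$LSD1, sim$genes)
loc <- as.data.frame(table(ann$class), stringsAsFactors = FALSE)
names(loc) <- c("class", "count")
loc$pct <- percent_of(loc$count, nrow(ann), 1)
print(loc)
write_result(loc, "lsd1_location_annotation.tsv")
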