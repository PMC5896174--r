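# Shared helpers for the numbered analysis drivers. Each driver can be run
# on its own: the simulated dataset is cached under scratch/ and rebuilt
# (deterministically, seed 11) when absent.

suppressPackageStartupMessages(library(glrscope))

ANALYSIS_SEED <- 11

get_sim <- function() {
  cache <- file.path("scratch", sprintf("sim_seed%d.rds", ANALYSIS_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  message("simulating study-scale dataset (seed ", ANALYSIS_SEED, ") ...")
  sim <- simulate_dataset(sim_config(seed = ANALYSIS_SEED))
  dir.create("scratch", showWarnings = FALSE)
  saveRDS(sim, cache)
  sim
}

write_result <- function(df, name) {
  dir.create("results", showWarnings = FALSE)
  path <- file.path("results", name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
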