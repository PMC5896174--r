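# Shared study-scale simulation, computed once per test run. The default
# configuration IS the study condition (n = 2,000 GFI1 peaks, planted
# coincidence 0.7/0.35, 1.5x acetylation effect at GLR sites, 0.8 log2fc
# DE effect); tests on planted-parameter recovery all read from here.
.sim_cache <- new.env(parent = emptyenv())

get_default_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_dataset(sim_config(seed = 424242))
  .sim_cache$sim
}

get_default_report <- function() {
  if (is.null(.sim_cache$report))
    .sim_cache$report <- run_pipeline(get_default_sim())
  .sim_cache$report
}

# small, fast configuration for structural tests (no claims about recovery
# precision): a 2 x 0.6 Mb genome
small_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2, chrom_length = 6e5, n_genes = 30,
         n_gfi1_peaks = 80, n_extra_lsd1 = 40, n_extra_rcor1 = 20),
    list(...))
  do.call(sim_config, args)
}
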