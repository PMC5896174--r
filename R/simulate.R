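#' Simulation configuration
#'
#' Parameters of the synthetic multi-factor ChIP-seq experiment. The
#' generator plants (i) coupled co-binding: each GFI1 peak receives an
#' LSD1 (resp. RCOR1) partner with probability increasing in its pileup
#' rank, the partner apex jittered around the GFI1 apex and truncated to
#' `jitter_max` so planted pairs always fall inside the ±500 bp
#' coincidence rule; (ii) a multiplicative treated-condition acetylation
#' effect confined to triple-occupied (GLR) sites; and (iii) an
#' expression log2 fold-change effect on genes nearest strong GLR sites.
#' A single seed drives independent per-stage substreams, so every output
#' is bit-identical across runs.
#'
#' @param seed master RNG seed.
#' @param n_chroms,chrom_length genome shape (chromosomes x bp).
#' @param n_genes number of genes, placed without overlap on both strands.
#' @param gene_length_range,n_exons_range gene geometry (bp, count).
#' @param n_gfi1_peaks number of GFI1 anchor peaks (all intergenic, at
#'   least `min_gene_distance` + 500 bp from any gene and `site_spacing`
#'   apart, so planted categories are unambiguous).
#' @param coincidence_lsd1,coincidence_rcor1 fraction of GFI1 peaks given
#'   an LSD1 / RCOR1 partner (the planted coincidence fractions).
#' @param strength_coupling logistic slope of partner probability in
#'   pileup rank (0 = no coupling; larger = strong peaks nearly always
#'   co-bound, mirroring the observed strongest-5% behaviour).
#' @param apex_jitter_sd,jitter_max partner apex jitter SD and hard
#'   truncation in bp (`jitter_max < 500` keeps planted pairs recoverable).
#' @param n_extra_lsd1,n_extra_rcor1 factor-only peaks placed > 1 kb from
#'   every GFI1 apex.
#' @param peak_width_range width range of factor peaks in bp.
#' @param pileup_base,pileup_mean peak strength model: `pileup = base +
#'   Exponential(mean)`.
#' @param mark_fraction_other fraction of non-triple GFI1 sites that also
#'   receive H3K9Ac/H3K4Me2 peaks (all triple-occupied sites receive them).
#' @param enhancer_fc_acetyl multiplicative treated/control effect on
#'   acetylation kernels at triple-occupied sites (1 = no effect).
#' @param kernel_halfwidth half-width in bp of the triangular (tent)
#'   coverage kernel whose height is the peak pileup.
#' @param background_depth mean of the per-base Poisson background depth.
#' @param read_length read length in bp used for count conversion.
#' @param de_effect planted log2fc added to genes nearest strong triple
#'   sites; `de_noise_sd` the per-gene Normal noise SD;
#'   `de_pileup_threshold` the strength cut defining "strong".
#' @param expr_meanlog,expr_sdlog log-normal baseline expression.
#' @param min_gene_distance intergenic margin used when placing sites.
#' @param site_spacing minimum spacing between candidate site positions.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 5, chrom_length = 6e6,
                       n_genes = 800,
                       gene_length_range = c(2000, 6000),
                       n_exons_range = c(2, 5),
                       n_gfi1_peaks = 2000,
                       coincidence_lsd1 = 0.7,
                       coincidence_rcor1 = 0.35,
                       strength_coupling = 6,
                       apex_jitter_sd = 100,
                       jitter_max = 400,
                       n_extra_lsd1 = 2000,
                       n_extra_rcor1 = 1000,
                       peak_width_range = c(300, 700),
                       pileup_base = 8, pileup_mean = 18,
                       mark_fraction_other = 0.5,
                       enhancer_fc_acetyl = 1.5,
                       kernel_halfwidth = 300,
                       background_depth = 0.2,
                       read_length = 50,
                       de_effect = 0.8,
                       de_noise_sd = 0.2,
                       de_pileup_threshold = 35,
                       expr_meanlog = log(50), expr_sdlog = 1,
                       min_gene_distance = 5000,
                       site_spacing = 2000) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
              n_gfi1_peaks >= 0, read_length > 0)
    if (coincidence_lsd1 < 0 || coincidence_lsd1 > 1 ||
        coincidence_rcor1 < 0 || coincidence_rcor1 > 1)
      stop_input("coincidence fractions must lie in [0, 1]")
    if (mark_fraction_other < 0 || mark_fraction_other > 1)
      stop_input("mark_fraction_other must lie in [0, 1]")
    if (enhancer_fc_acetyl <= 0) stop_input("enhancer_fc_acetyl must be > 0")
    if (jitter_max >= 500)
      stop_input("jitter_max must stay below the 500 bp coincidence window")
    if (background_depth < 0) stop_input("background_depth must be >= 0")
  })
  structure(cfg, class = "SimulationConfig")
}

#' Load a simulation configuration from YAML
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return a `SimulationConfig`.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop_input("unknown simulation config keys: %s",
               paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Generate the synthetic genome
#'
#' Places `n_genes` non-overlapping genes (both strands) by partitioning
#' each chromosome into equal segments and drawing one gene per segment,
#' which guarantees non-overlap and leaves intergenic room for enhancer
#' sites. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (a [gene_table()]) and `chrom_sizes`
#'   (named vector).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  seeds <- derive_seeds(config$seed, 4)
  set.seed(seeds[1])
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms), chroms)
  if (config$n_genes == 0)
    return(list(genes = gene_table(data.frame(
      gene_id = character(), gene_name = character(), chrom = character(),
      strand = character(), start = numeric(), end = numeric(),
      biotype = character(), exons = I(list()))),
      chrom_sizes = chrom_sizes))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  max_len <- config$gene_length_range[2]
  rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    seg <- config$chrom_length / k
    if (seg < max_len + 2 * config$site_spacing)
      stop_input("genes cannot fit: %d genes of up to %d bp on a %g bp chromosome",
                 k, max_len, config$chrom_length)
    for (j in seq_len(k)) {
      gi <- gi + 1L
      len <- round(stats::runif(1, config$gene_length_range[1], max_len))
      slack <- seg - len - 2 * config$site_spacing
      start <- floor((j - 1) * seg + config$site_spacing + stats::runif(1) * slack)
      n_ex <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]), 1)
      # alternating exon/intron blocks covering the locus
      cuts <- sort(stats::runif(2 * n_ex - 2, 0, 1))
      bounds <- round(c(0, cuts, 1) * len)
      ex_start <- start + bounds[seq(1, 2 * n_ex - 1, by = 2)]
      ex_end <- start + pmax(bounds[seq(2, 2 * n_ex, by = 2)],
                             bounds[seq(1, 2 * n_ex - 1, by = 2)] + 1)
      ex_end <- pmin(ex_end, start + len)
      keep <- ex_start < ex_end
      rows[[gi]] <- data.frame(
        gene_id = sprintf("G%04d", gi),
        gene_name = sprintf("GENE%04d", gi),
        chrom = chroms[ci],
        strand = sample(c("+", "-"), 1),
        start = start, end = start + len,
        biotype = if (stats::runif(1) < 0.95) "protein_coding" else "lncRNA",
        exons = I(list(data.frame(start = ex_start[keep], end = ex_end[keep]))),
        stringsAsFactors = FALSE)
    }
  }
  list(genes = gene_table(do.call(rbind, rows)), chrom_sizes = chrom_sizes)
}

#' Generate coupled multi-factor peak sets
#'
#' GFI1 anchor peaks are placed on an intergenic grid (far from genes and
#' from each other); each receives LSD1/RCOR1 partners with rank-coupled
#' probability and truncated apex jitter; factor-only LSD1/RCOR1 peaks
#' are placed on unused grid positions (> 1 kb from every GFI1 apex);
#' H3K9Ac and H3K4Me2 peaks are placed around all triple-occupied sites
#' plus a configured fraction of the remaining GFI1 sites.
#'
#' @param config a [sim_config()].
#' @param genome result of [generate_genome()].
#' @return list with `peaks` (named list of [peak_set()]: GFI1, LSD1,
#'   RCOR1, H3K9Ac, H3K4Me2) and `manifest` (ground truth: per-site
#'   partner assignments, categories, mark placement).
#' @export
generate_peak_sets <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  seeds <- derive_seeds(config$seed, 4)
  set.seed(seeds[2])
  genes <- genome$genes
  margin <- config$min_gene_distance + 500
  slots <- intergenic_grid(genome$chrom_sizes, genes, margin,
                           config$site_spacing)
  n_sites <- config$n_gfi1_peaks
  n_extra <- config$n_extra_lsd1 + config$n_extra_rcor1
  if (nrow(slots) < n_sites + n_extra)
    stop_input("genome too small: %d candidate site positions for %d peaks",
               nrow(slots), n_sites + n_extra)
  pick <- sample.int(nrow(slots), n_sites + n_extra)
  g_pos <- slots[pick[seq_len(n_sites)], , drop = FALSE]
  extra_pos <- slots[pick[n_sites + seq_len(n_extra)], , drop = FALSE]

  pileup <- config$pileup_base + stats::rexp(n_sites, 1 / config$pileup_mean)
  u <- rank(pileup, ties.method = "first") / n_sites
  p_l <- coupled_probability(u, config$coincidence_lsd1, config$strength_coupling)
  p_r <- coupled_probability(u, config$coincidence_rcor1, config$strength_coupling)
  has_l <- stats::runif(n_sites) < p_l
  has_r <- stats::runif(n_sites) < p_r

  mk_peaks <- function(chrom, apex, pileup, prefix) {
    n <- length(apex)
    if (!n) return(data.frame(chrom = character(), start = numeric(),
                              end = numeric(), apex = numeric(),
                              pileup = numeric(), peak_id = character()))
    w <- round(stats::runif(n, config$peak_width_range[1],
                            config$peak_width_range[2]))
    start <- pmax(apex - w %/% 2, 0)
    data.frame(chrom = chrom, start = start, end = start + w, apex = apex,
               pileup = pileup,
               peak_id = sprintf("%s_%05d", prefix, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  jitter <- function(n) {
    j <- round(stats::rnorm(n, 0, config$apex_jitter_sd))
    pmin(pmax(j, -config$jitter_max), config$jitter_max)
  }
  gfi1_df <- mk_peaks(g_pos$chrom, g_pos$pos, pileup, "GFI1")
  l_apex <- g_pos$pos[has_l] + jitter(sum(has_l))
  r_apex <- g_pos$pos[has_r] + jitter(sum(has_r))
  l_pile <- pileup[has_l] * stats::runif(sum(has_l), 0.6, 1.1)
  r_pile <- pileup[has_r] * stats::runif(sum(has_r), 0.6, 1.1)
  n_xl <- config$n_extra_lsd1
  extra_pile <- function(n) 5 + stats::rexp(n, 1 / 10)
  lsd1_df <- rbind(
    mk_peaks(g_pos$chrom[has_l], l_apex, l_pile, "LSD1p"),
    mk_peaks(extra_pos$chrom[seq_len(n_xl)], extra_pos$pos[seq_len(n_xl)],
             extra_pile(n_xl), "LSD1x"))
  rcor1_df <- rbind(
    mk_peaks(g_pos$chrom[has_r], r_apex, r_pile, "RCOR1p"),
    mk_peaks(extra_pos$chrom[n_xl + seq_len(config$n_extra_rcor1)],
             extra_pos$pos[n_xl + seq_len(config$n_extra_rcor1)],
             extra_pile(config$n_extra_rcor1), "RCOR1x"))

  triple <- has_l & has_r
  marked <- triple | (stats::runif(n_sites) < config$mark_fraction_other)
  msel <- which(marked)
  k9_apex <- g_pos$pos[msel] + sample(-100:100, length(msel), replace = TRUE)
  k4_apex <- g_pos$pos[msel] + sample(-200:200, length(msel), replace = TRUE)
  mark_pile <- function(n) 10 + stats::rexp(n, 1 / 15)
  k9_w <- round(stats::runif(length(msel), 1000, 1400))
  k4_w <- round(stats::runif(length(msel), 1400, 1800))
  k9_df <- data.frame(chrom = g_pos$chrom[msel],
                      start = pmax(k9_apex - k9_w %/% 2, 0),
                      apex = k9_apex, pileup = mark_pile(length(msel)),
                      peak_id = sprintf("K9_%05d", seq_along(msel)),
                      stringsAsFactors = FALSE)
  k9_df$end <- k9_df$start + k9_w
  k4_df <- data.frame(chrom = g_pos$chrom[msel],
                      start = pmax(k4_apex - k4_w %/% 2, 0),
                      apex = k4_apex, pileup = mark_pile(length(msel)),
                      peak_id = sprintf("K4_%05d", seq_along(msel)),
                      stringsAsFactors = FALSE)
  k4_df$end <- k4_df$start + k4_w

  manifest_sites <- data.frame(
    site_id = gfi1_df$peak_id, chrom = g_pos$chrom, apex = g_pos$pos,
    pileup = pileup, p_lsd1 = p_l, p_rcor1 = p_r,
    has_lsd1 = has_l, has_rcor1 = has_r, triple = triple,
    strong = pileup >= config$de_pileup_threshold,
    marked = marked,
    lsd1_id = NA_character_, rcor1_id = NA_character_,
    h3k9ac_id = NA_character_, h3k4me2_id = NA_character_,
    stringsAsFactors = FALSE)
  manifest_sites$lsd1_id[has_l] <- lsd1_df$peak_id[seq_len(sum(has_l))]
  manifest_sites$rcor1_id[has_r] <- rcor1_df$peak_id[seq_len(sum(has_r))]
  manifest_sites$h3k9ac_id[msel] <- k9_df$peak_id
  manifest_sites$h3k4me2_id[msel] <- k4_df$peak_id
  manifest_sites$category <- with(manifest_sites, ifelse(
    triple, "GLR", ifelse(has_lsd1, "GL", ifelse(has_rcor1, "GR", "G"))))

  peaks <- list(
    GFI1 = peak_set(gfi1_df, factor = "GFI1", condition = "DMSO"),
    LSD1 = peak_set(lsd1_df, factor = "LSD1", condition = "DMSO"),
    RCOR1 = peak_set(rcor1_df, factor = "RCOR1", condition = "DMSO"),
    H3K9Ac = peak_set(k9_df[, c("chrom", "start", "end", "apex", "pileup",
                                "peak_id")], factor = "H3K9Ac", condition = "DMSO"),
    H3K4Me2 = peak_set(k4_df[, c("chrom", "start", "end", "apex", "pileup",
                                 "peak_id")], factor = "H3K4Me2", condition = "DMSO"))
  list(peaks = peaks, manifest = list(sites = manifest_sites))
}

# candidate intergenic positions: a site_spacing grid over the complement
# of gene loci extended by `margin`; the caller samples from it
intergenic_grid <- function(chrom_sizes, genes, margin, spacing) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g)) {
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(g$start - margin, 0) + 1, end = pmin(g$end + margin, L)))
      free <- IRanges::gaps(ir, start = 1, end = L)
    } else {
      free <- IRanges::IRanges(start = 1, end = L)
    }
    pos <- unlist(lapply(seq_along(free), function(i) {
      s <- IRanges::start(free)[i] - 1 + 1000
      e <- IRanges::end(free)[i] - 1000
      if (e - s < spacing) return(numeric(0))
      seq(s, e, by = spacing)
    }))
    if (length(pos)) out[[ch]] <- data.frame(chrom = ch, pos = pos)
  }
  if (!length(out)) return(data.frame(chrom = character(), pos = numeric()))
  do.call(rbind, out)
}

# logistic rank coupling with the intercept solved so the mean partner
# probability equals the target coincidence fraction
coupled_probability <- function(u, target, slope) {
  if (target <= 0) return(rep(0, length(u)))
  if (target >= 1) return(rep(1, length(u)))
  if (slope == 0) return(rep(target, length(u)))
  f <- function(a) mean(stats::plogis(a + slope * u)) - target
  a <- stats::uniroot(f, c(-50, 50))$root
  stats::plogis(a + slope * u)
}

#' Generate two-condition coverage tracks
#'
#' Per-base depth = Poisson background noise plus a triangular (tent)
#' kernel of height equal to the peak pileup at each peak apex of the
#' track's mark. In the treated condition, acetylation kernels at
#' triple-occupied sites are scaled by `enhancer_fc_acetyl`; everything
#' else is unchanged (fresh noise is drawn per condition). Both
#' conditions of a mark share one `total_mapped_reads` (depth-matched
#' libraries) so RPKM comparisons sit on the same normalisation basis.
#'
#' @param config a [sim_config()].
#' @param genome result of [generate_genome()].
#' @param peak_sets result of [generate_peak_sets()].
#' @param marks which marks to build tracks for (default H3K9Ac and
#'   H3K4Me2); acetylation marks (name containing "Ac") receive the
#'   planted treated-condition effect.
#' @param conditions condition labels, control first.
#' @return named list `mark.condition` of [coverage_track()] objects.
#' @export
generate_coverage <- function(config, genome, peak_sets,
                              marks = c("H3K9Ac", "H3K4Me2"),
                              conditions = c("DMSO", "OG86")) {
  stopifnot(inherits(config, "SimulationConfig"))
  seeds <- derive_seeds(config$seed, 4)
  set.seed(seeds[3])
  man <- peak_sets$manifest$sites
  tracks <- list()
  for (mark in marks) {
    pk <- peak_sets$peaks[[mark]]
    if (is.null(pk)) stop_input("no peak set for mark '%s'", mark)
    is_acetyl <- grepl("Ac", mark, fixed = TRUE)
    # which of this mark's peaks sit at triple-occupied sites
    id_col <- if (mark == "H3K9Ac") "h3k9ac_id" else
      if (mark == "H3K4Me2") "h3k4me2_id" else NA
    triple_ids <- if (!is.na(id_col))
      man[[id_col]][man$triple & !is.na(man[[id_col]])] else character(0)
    shared_total <- NULL
    for (cond in conditions) {
      fc <- if (is_acetyl && cond != conditions[1]) config$enhancer_fc_acetyl else 1
      height <- pk$pileup * ifelse(pk$peak_id %in% triple_ids, fc, 1)
      depths <- list()
      for (ch in names(genome$chrom_sizes)) {
        L <- genome$chrom_sizes[[ch]]
        v <- stats::rpois(L, config$background_depth)
        sel <- which(pk$chrom == ch)
        v <- add_tent_kernels(v, pk$apex[sel], height[sel],
                              config$kernel_halfwidth)
        depths[[ch]] <- S4Vectors::Rle(v)
      }
      if (is.null(shared_total))
        shared_total <- max(round(sum(vapply(depths, function(r)
          sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 0)) /
            config$read_length), 1)
      tracks[[paste(mark, cond, sep = ".")]] <- coverage_track(
        depths, total_mapped_reads = shared_total,
        read_length = config$read_length, mark = mark, condition = cond,
        chrom_sizes = genome$chrom_sizes)
    }
  }
  tracks
}

# add tent kernels (height at apex, linear to zero at +/- halfwidth) onto a
# per-base depth vector; positions are 0-based, vector index is pos + 1
add_tent_kernels <- function(v, apexes, heights, halfwidth) {
  L <- length(v)
  for (i in seq_along(apexes)) {
    a <- apexes[i]
    lo <- max(a - halfwidth + 1, 0); hi <- min(a + halfwidth - 1, L - 1)
    if (lo > hi) next
    x <- lo:hi
    v[x + 1] <- v[x + 1] + heights[i] * (1 - abs(x - a) / halfwidth)
  }
  v
}

#' Generate the expression table
#'
#' Baseline expression is log-normal. Genes nearest a triple-occupied
#' site whose GFI1 pileup meets `de_pileup_threshold` receive a planted
#' `de_effect` log2 fold change plus Normal noise; all other genes get
#' Normal(0, `de_noise_sd`) noise only.
#'
#' @param config a [sim_config()].
#' @param genome result of [generate_genome()].
#' @param peak_sets result of [generate_peak_sets()] (supplies the
#'   manifest; target genes are added to it).
#' @return list with `expression` (an [expression_table()]) and
#'   `manifest_genes` (data.frame: gene_id, target flag, planted_log2fc).
#' @export
generate_expression <- function(config, genome, peak_sets) {
  stopifnot(inherits(config, "SimulationConfig"))
  seeds <- derive_seeds(config$seed, 4)
  set.seed(seeds[4])
  genes <- genome$genes
  man <- peak_sets$manifest$sites
  target_genes <- character(0)
  if (nrow(genes)) {
    strong_triple <- man[man$triple & man$strong, , drop = FALSE]
    if (nrow(strong_triple)) {
      nt <- nearest_tss(strong_triple$chrom, strong_triple$apex, genes,
                        error_on_missing = FALSE)
      target_genes <- sort(unique(nt$gene_id[!is.na(nt$gene_id)]))
    }
  }
  n <- nrow(genes)
  base <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  lfc <- stats::rnorm(n, 0, config$de_noise_sd)
  is_target <- genes$gene_id %in% target_genes
  lfc[is_target] <- lfc[is_target] + config$de_effect
  expr <- expression_table(data.frame(
    gene_id = genes$gene_id,
    expr_ctrl = base,
    expr_trt = base * 2^lfc,
    log2fc = lfc, expressed = TRUE, stringsAsFactors = FALSE))
  list(expression = expr,
       manifest_genes = data.frame(gene_id = genes$gene_id,
                                   target = is_target,
                                   planted_log2fc = ifelse(is_target,
                                                           config$de_effect, 0),
                                   stringsAsFactors = FALSE))
}

#' Run the full simulation
#'
#' Genome, peak sets, coverage and expression in one call, optionally
#' written to disk in the standard formats (narrowPeak, GTF, bedGraph,
#' TSV, manifest JSON) so every emitted file round-trips through the
#' package readers.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory to write files into.
#' @param coverage logical; build coverage tracks (the slowest stage)?
#' @param marks marks passed to [generate_coverage()].
#' @return list with `config`, `genes`, `chrom_sizes`, `peaks`, `tracks`
#'   (or `NULL`), `expression`, `manifest` (sites, genes and planted
#'   parameters).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL,
                             coverage = TRUE,
                             marks = c("H3K9Ac", "H3K4Me2")) {
  genome <- generate_genome(config)
  ps <- generate_peak_sets(config, genome)
  tracks <- if (coverage) generate_coverage(config, genome, ps, marks = marks)
            else NULL
  ex <- generate_expression(config, genome, ps)
  manifest <- list(sites = ps$manifest$sites,
                   genes = ex$manifest_genes,
                   planted = list(
                     coincidence_lsd1 = config$coincidence_lsd1,
                     coincidence_rcor1 = config$coincidence_rcor1,
                     enhancer_fc_acetyl = config$enhancer_fc_acetyl,
                     de_effect = config$de_effect),
                   seed = config$seed)
  out <- list(config = config, genes = genome$genes,
              chrom_sizes = genome$chrom_sizes, peaks = ps$peaks,
              tracks = tracks, expression = ex$expression,
              manifest = manifest)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$peaks))
    write_peaks(sim$peaks[[nm]], file.path(out_dir, paste0(nm, ".narrowPeak")))
  write_genes(sim$genes, file.path(out_dir, "genes.gtf"))
  write_expression(sim$expression, file.path(out_dir, "expression.tsv"))
  utils::write.table(
    data.frame(chrom = names(sim$chrom_sizes), size = sim$chrom_sizes),
    file.path(out_dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(sim$tracks))
    for (nm in names(sim$tracks))
      write_coverage(sim$tracks[[nm]],
                     file.path(out_dir, paste0(nm, ".bedGraph")))
  jsonlite::write_json(
    list(sites = sim$manifest$sites, genes = sim$manifest$genes,
         planted = sim$manifest$planted, seed = sim$manifest$seed),
    file.path(out_dir, "manifest.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
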