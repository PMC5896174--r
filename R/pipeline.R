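#' Pipeline analysis parameters
#'
#' The thresholds used across the analysis stages, with the defaults the
#' study design prescribes: 500 bp apex coincidence window, 1 kb promoter
#' half-width, 5 kb enhancer-to-gene distance, pileup 35 strength
#' threshold, 0.5 DE log2fc threshold, strongest-5% stratification,
#' 1 kb signal flank with a 0.5 RPKM pseudocount.
#'
#' @param window coincidence window in bp.
#' @param top_fraction strongest fraction for stratified coincidence.
#' @param promoter_halfwidth promoter half-width in bp.
#' @param min_gene_distance enhancer distance-to-gene minimum in bp.
#' @param pileup_threshold strong/weak site cut-off.
#' @param de_threshold DE log2fc threshold.
#' @param flank signal window half-width in bp.
#' @param pseudocount RPKM pseudocount for per-site log2fc.
#' @param n_perm GSEA permutations.
#' @return a named list of validated parameters.
#' @export
pipeline_params <- function(window = 500, top_fraction = 0.05,
                            promoter_halfwidth = 1000,
                            min_gene_distance = 5000,
                            pileup_threshold = 35, de_threshold = 0.5,
                            flank = 1000, pseudocount = 0.5,
                            n_perm = 1000) {
  p <- as.list(environment())
  if (any(vapply(p, function(x) !is.numeric(x) || x <= 0, TRUE)))
    stop_input("all pipeline parameters must be positive numbers")
  p
}

#' Run the integrated analysis pipeline
#'
#' Simulate (or accept) a dataset, then run the full analysis:
#' co-occupancy summaries (overall and strongest-5%), category
#' partitioning, active-enhancer calling, condition fold change of
#' acetylation signal at GLR versus other sites, DE-gene thresholding,
#' strength-stratified expression and GSEA of the GLR-linked gene set.
#' Deterministic given the simulation seed. When the dataset carries a
#' ground-truth manifest the report also tabulates planted versus
#' recovered parameters.
#'
#' @param sim a [simulate_dataset()] result (or a compatible list with
#'   `peaks`, `genes`, `tracks`, `expression`).
#' @param params a [pipeline_params()] list.
#' @param out_dir optional directory: stage outputs are written as
#'   TSV/JSON and the report as `report.json`.
#' @return a `RunReport` list with per-stage summaries.
#' @export
run_pipeline <- function(sim, params = pipeline_params(), out_dir = NULL) {
  t0 <- Sys.time()
  pk <- sim$peaks
  stopifnot(all(c("GFI1", "LSD1", "RCOR1") %in% names(pk)))

  ## stage 1: co-occupancy
  coin <- rbind(
    coincidence_summary(pk$GFI1, pk$LSD1, params$window),
    coincidence_summary(pk$GFI1, pk$RCOR1, params$window),
    stratified_coincidence(pk$GFI1, pk$LSD1, params$window, params$top_fraction),
    stratified_coincidence(pk$GFI1, pk$RCOR1, params$window, params$top_fraction))
  coin$stratum <- c("all", "all", sprintf("top%g%%", 100 * params$top_fraction),
                    sprintf("top%g%%", 100 * params$top_fraction))
  assignments <- partition_categories(pk$GFI1, pk$LSD1, pk$RCOR1, params$window)
  part <- partition_report(assignments, digits = 1)
  glr_sites <- assignments[assignments$category == "GLR", , drop = FALSE]
  glr_sites$center <- glr_sites$apex

  ## stage 2: enhancers
  enhancers <- NULL
  if (all(c("H3K9Ac", "H3K4Me2") %in% names(pk)) && nrow(sim$genes) > 0) {
    enhancers <- call_active_enhancers(pk$H3K9Ac, pk$H3K4Me2, sim$genes,
                                       min_gene_distance = params$min_gene_distance,
                                       lsd1 = pk$LSD1, window = params$window)
  }

  ## stage 3: signal fold changes at GLR vs other marked sites
  signal <- NULL
  if (!is.null(sim$tracks)) {
    acetyl <- grep("Ac\\.", names(sim$tracks), value = TRUE)
    mark_names <- unique(sub("\\..*$", "", names(sim$tracks)))
    conds <- unique(sub("^.*\\.", "", names(sim$tracks)))
    other_sites <- assignments[assignments$category != "GLR", , drop = FALSE]
    other_sites$center <- other_sites$apex
    # restrict to sites that carry the histone marks at all: those near an
    # H3K9Ac peak (marked sites), so "no change" is measured where there is
    # signal to measure
    if (nrow(other_sites) && "H3K9Ac" %in% names(pk)) {
      osp <- peak_set(data.frame(chrom = other_sites$chrom,
                                 start = other_sites$start,
                                 end = other_sites$end,
                                 apex = other_sites$apex,
                                 pileup = other_sites$pileup,
                                 peak_id = other_sites$site_id))
      near_mark <- find_partners(osp, pk$H3K9Ac, params$window)
      other_sites <- other_sites[!is.na(near_mark$partner_id), , drop = FALSE]
    }
    signal <- list()
    for (mk in mark_names) {
      ctrl <- sim$tracks[[paste(mk, conds[1], sep = ".")]]
      trt <- sim$tracks[[paste(mk, conds[2], sep = ".")]]
      if (is.null(ctrl) || is.null(trt)) next
      fc_glr <- if (nrow(glr_sites))
        fold_change_summary(ctrl, trt, glr_sites, params$flank,
                            params$pseudocount) else NULL
      fc_other <- if (nrow(other_sites))
        fold_change_summary(ctrl, trt, other_sites, params$flank,
                            params$pseudocount) else NULL
      signal[[mk]] <- data.frame(
        mark = mk,
        site_set = c("GLR", "other"),
        n_sites = c(nrow(glr_sites), nrow(other_sites)),
        percent_change = c(fc_glr$percent_change %||% NA_real_,
                           fc_other$percent_change %||% NA_real_))
    }
    signal <- do.call(rbind, signal)
    rownames(signal) <- NULL
  }

  ## stage 4: expression integration
  expr <- sim$expression
  de <- select_de_genes(expr, params$de_threshold)
  ranked <- stats::setNames(expr$log2fc[expr$expressed],
                            expr$gene_id[expr$expressed])
  glr_genes <- if (nrow(glr_sites)) peak_gene_set(glr_sites, sim$genes)
               else character(0)
  enr <- NULL
  strata <- NULL
  if (length(glr_genes) > 0 && length(glr_genes) < length(ranked)) {
    enr <- normalized_enrichment(ranked, glr_genes, n_perm = params$n_perm,
                                 seed = derive_seeds(sim$config$seed, 5)[5])
    enr$set_name <- "GLR_linked_genes"
  }
  if (nrow(glr_sites)) {
    strata <- tryCatch(
      strength_stratified_expression(glr_sites, expr, sim$genes,
                                     params$pileup_threshold),
      error = function(e) NULL)
  }

  ## recovery against the planted truth, when available
  recovery <- NULL
  if (!is.null(sim$manifest)) {
    man <- sim$manifest
    est_l <- coin$fraction[1]; est_r <- coin$fraction[2]
    tgt <- man$genes$gene_id[man$genes$target]
    de_recovered <- if (length(tgt))
      mean(expr$log2fc[match(tgt, expr$gene_id)]) else NA_real_
    acetyl_mark <- if (!is.null(signal)) intersect(unique(signal$mark), "H3K9Ac")
                   else character(0)
    pc_glr <- if (length(acetyl_mark))
      signal$percent_change[signal$mark == acetyl_mark & signal$site_set == "GLR"]
      else NA_real_
    pc_other <- if (length(acetyl_mark))
      signal$percent_change[signal$mark == acetyl_mark & signal$site_set == "other"]
      else NA_real_
    recovery <- data.frame(
      quantity = c("coincidence_lsd1", "coincidence_rcor1",
                   "acetyl_percent_change_glr", "acetyl_percent_change_other",
                   "de_effect"),
      planted = c(man$planted$coincidence_lsd1, man$planted$coincidence_rcor1,
                  100 * (man$planted$enhancer_fc_acetyl - 1), 0,
                  man$planted$de_effect),
      estimated = c(est_l, est_r, pc_glr, pc_other, de_recovered))
  }

  report <- list(
    params = params,
    config = if (!is.null(sim$config)) unclass(sim$config) else NULL,
    peak_counts = vapply(pk, nrow, 0L),
    coincidence = coin,
    partition = part,
    n_glr_sites = nrow(glr_sites),
    enhancers = if (!is.null(enhancers)) list(
      n = nrow(enhancers),
      n_lsd1_bound = if ("lsd1_bound" %in% names(enhancers))
        sum(enhancers$lsd1_bound) else NA_integer_,
      pct_lsd1_bound = if ("lsd1_bound" %in% names(enhancers) && nrow(enhancers))
        percent_of(sum(enhancers$lsd1_bound), nrow(enhancers)) else NA_real_)
      else NULL,
    signal = signal,
    de = list(n_up = length(de$up), n_down = length(de$down),
              n_expressed = de$n_expressed),
    glr_gene_set_size = length(glr_genes),
    enrichment = if (!is.null(enr))
      list(set = enr$set_name, n_genes = enr$n_genes, es = enr$es,
           nes = enr$nes, p_value = enr$p_value, n_perm = enr$n_perm) else NULL,
    strata = if (!is.null(strata)) list(
      means = as.list(strata$means),
      anova_p = strata$comparison$anova$p_value,
      comparisons = strata$comparison$comparisons) else NULL,
    recovery = recovery,
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    version = as.character(utils::packageVersion("glrscope")))
  class(report) <- "RunReport"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(coin, file.path(out_dir, "coincidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(part$table, file.path(out_dir, "partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(assignments),
                       file.path(out_dir, "categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enhancers))
      utils::write.table(enhancers, file.path(out_dir, "enhancers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(signal))
      utils::write.table(signal, file.path(out_dir, "signal_changes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(recovery))
      utils::write.table(recovery, file.path(out_dir, "recovery.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", force = TRUE)
  }
  report
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$timestamp <- NULL
  r$elapsed_sec <- NULL
  r
}

#' @export
print.RunReport <- function(x, ...) {
  cat("glrscope run report\n")
  cat(sprintf("  peaks: %s\n",
              paste(sprintf("%s=%d", names(x$peak_counts), x$peak_counts),
                    collapse = ", ")))
  for (i in seq_len(nrow(x$coincidence)))
    cat(sprintf("  %s of %s peaks (%s) coincident with %s (window ±%g bp): %s%%\n",
                x$coincidence$n_coincident[i], x$coincidence$n_query[i],
                x$coincidence$stratum[i], x$coincidence$target_factor[i],
                x$params$window, x$coincidence$percent[i]))
  cat(sprintf("  category sites: %d (GLR: %d)\n",
              x$partition$totals[["sites"]], x$n_glr_sites))
  if (!is.null(x$enhancers))
    cat(sprintf("  active intergenic enhancers: %d (%s%% LSD1-bound)\n",
                x$enhancers$n, x$enhancers$pct_lsd1_bound))
  if (!is.null(x$signal))
    for (i in seq_len(nrow(x$signal)))
      cat(sprintf("  %s signal change at %s sites (n=%d): %+.1f%%\n",
                  x$signal$mark[i], x$signal$site_set[i], x$signal$n_sites[i],
                  x$signal$percent_change[i]))
  cat(sprintf("  DE genes at |log2FC| >= %.2g: %d up, %d down of %d expressed\n",
              x$params$de_threshold, x$de$n_up, x$de$n_down, x$de$n_expressed))
  if (!is.null(x$enrichment))
    cat(sprintf("  GSEA %s (n=%d): ES=%.3f NES=%.2f p=%.3g\n",
                x$enrichment$set, x$enrichment$n_genes, x$enrichment$es,
                x$enrichment$nes, x$enrichment$p_value))
  if (!is.null(x$recovery)) {
    cat("  parameter recovery (planted -> estimated):\n")
    for (i in seq_len(nrow(x$recovery)))
      cat(sprintf("    %s: %.3g -> %.3g\n", x$recovery$quantity[i],
                  x$recovery$planted[i], x$recovery$estimated[i]))
  }
  invisible(x)
}
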