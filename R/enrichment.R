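#' Threshold differentially expressed genes
#'
#' Splits expressed genes into up- and downregulated sets at an inclusive
#' log2 fold-change threshold (default 0.5, the rule yielding the printed
#' counts of up/down genes among expressed protein-coding genes).
#'
#' @param expr an [expression_table()].
#' @param threshold positive log2fc cut-off; genes with `log2fc >=
#'   threshold` are up, `log2fc <= -threshold` down.
#' @return list with character vectors `up` and `down` (disjoint), plus
#'   `n_expressed`.
#' @export
select_de_genes <- function(expr, threshold = 0.5) {
  stopifnot(inherits(expr, "ExpressionTable"))
  if (threshold <= 0) stop_input("DE threshold must be positive")
  e <- expr[expr$expressed, , drop = FALSE]
  list(up = e$gene_id[e$log2fc >= threshold],
       down = e$gene_id[e$log2fc <= -threshold],
       n_expressed = nrow(e))
}

# order a named metric vector into the ranked list (descending metric,
# deterministic tie-break by gene id)
rank_metric <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene_id", "metric") %in% names(ranked)))
    v <- stats::setNames(ranked$metric, ranked$gene_id)
  } else {
    v <- ranked
  }
  if (is.null(names(v)) || any(!nzchar(names(v))))
    stop_input("ranked list must be a named metric vector (names = gene ids)")
  if (anyDuplicated(names(v))) stop_input("duplicate genes in ranked list")
  if (any(!is.finite(v))) stop_input("ranking metric must be finite")
  v[order(-v, names(v), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum enrichment of a gene set within a list ranked by a metric
#' (typically expression log2 fold change, descending). At each hit the
#' sum increments by `|metric|^weight_exponent` normalised by the sum over
#' all hits; at each miss it decrements by `1 / (N - N_hits)`. The
#' enrichment score (ES) is the extremum of the running sum; the leading
#' edge contains the hits at or before the extremum (at or after it for
#' negative ES). With `weight_exponent = 0` the |ES| equals the classical
#' two-sample KS statistic between hit and miss rank distributions.
#'
#' @param ranked named numeric vector (names = gene ids, values = metric)
#'   or data frame with `gene_id`/`metric`; re-sorted descending
#'   internally with ties broken by gene id.
#' @param gene_set character vector of gene ids; the intersection with the
#'   ranked list must be non-empty and proper.
#' @param weight_exponent hit-weight exponent (default 1; 0 = unweighted).
#' @return list with `es`, `running` (length-N running sum),
#'   `leading_edge` (gene ids), `hit_positions`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  v <- rank_metric(ranked)
  N <- length(v)
  m <- names(v) %in% gene_set
  nh <- sum(m)
  if (nh == 0 || nh == N)
    stop_input("gene set intersection with the ranked list must be non-empty and proper (got %d of %d)",
               nh, N)
  w <- abs(v)^weight_exponent
  wh <- w * m
  tot <- sum(wh)
  if (tot == 0) { wh <- as.numeric(m); tot <- nh }  # all-zero hit weights
  running <- unname(cumsum(wh) / tot - cumsum(!m) / (N - nh))
  i <- which.max(abs(running))
  es <- running[i]
  hits <- which(m)
  leading <- if (es >= 0) names(v)[hits[hits <= i]] else names(v)[hits[hits >= i]]
  list(es = es, running = running, leading_edge = leading,
       hit_positions = hits)
}

# ES only, from hit positions within a ranked weight vector; used for the
# permutation null (same running-sum definition as enrichment_score)
es_from_positions <- function(w, N, hit_pos) {
  hit_pos <- sort(hit_pos)
  nh <- length(hit_pos)
  wh <- w[hit_pos]
  tot <- sum(wh)
  if (tot == 0) { wh <- rep(1, nh); tot <- nh }
  cw <- cumsum(wh) / tot
  miss_before <- (hit_pos - seq_len(nh)) / (N - nh)
  at_hit <- cw - miss_before            # running sum just after each hit
  before_hit <- c(0, cw[-nh]) - (hit_pos - 1 - (seq_len(nh) - 1)) / (N - nh)
  cand <- unname(c(at_hit, before_hit))
  cand[which.max(abs(cand))]
}

#' Permutation-normalised enrichment
#'
#' Builds a null distribution by drawing random gene sets of equal size
#' (without replacement) from the ranked genes. The normalised enrichment
#' score is the ES divided by the mean |null ES| of matching sign; the
#' nominal p-value is the same-sign null exceedance fraction with one
#' pseudo-observation. A seed is required so results are reproducible.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed integer RNG seed (required).
#' @return an `EnrichmentResult` list: `set_name`, `n_genes`, `es`, `nes`,
#'   `p_value`, `fdr` (equal to `p_value` for a single set; adjusted by
#'   [run_enrichment()] across sets), `leading_edge`, `n_perm`, `seed`.
#' @export
normalized_enrichment <- function(ranked, gene_set, n_perm = 1000, seed,
                                  weight_exponent = 1) {
  if (missing(seed) || is.null(seed))
    stop_input("normalized_enrichment requires an explicit seed")
  if (n_perm < 100)
    warning("n_perm < 100: permutation p-values will be coarse", call. = FALSE)
  v <- rank_metric(ranked)
  obs <- enrichment_score(v, gene_set, weight_exponent)
  N <- length(v)
  nh <- length(obs$hit_positions)
  w <- abs(v)^weight_exponent
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(i)
    es_from_positions(w, N, sample.int(N, nh)), 0)
  same <- null_es[sign(null_es) == sign(obs$es)]
  if (length(same)) {
    nes <- obs$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  } else {
    nes <- NA_real_
    p <- 1 / (1 + 0)
  }
  structure(list(set_name = NA_character_, n_genes = nh, es = obs$es,
                 nes = nes, p_value = p, fdr = p,
                 leading_edge = obs$leading_edge,
                 n_perm = n_perm, seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult%s: n=%d, ES=%.3f, NES=%.3f, p=%.4g, FDR=%.4g (%d permutations)\n",
              if (is.na(x$set_name)) "" else paste0(" [", x$set_name, "]"),
              x$n_genes, x$es, x$nes, x$p_value, x$fdr, x$n_perm))
  invisible(x)
}

#' Enrichment of several gene sets with BH FDR
#'
#' Runs [normalized_enrichment()] for each set against the same ranked
#' list and applies Benjamini-Hochberg adjustment across the nominal
#' p-values.
#'
#' @inheritParams normalized_enrichment
#' @param gene_sets named list of gene id vectors.
#' @return list of `EnrichmentResult` objects (named), `fdr` filled in.
#' @export
run_enrichment <- function(ranked, gene_sets, n_perm = 1000, seed,
                           weight_exponent = 1) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  seeds <- derive_seeds(seed, length(gene_sets))
  res <- Map(function(gs, nm, s) {
    r <- normalized_enrichment(ranked, gs, n_perm = n_perm, seed = s,
                               weight_exponent = weight_exponent)
    r$set_name <- nm
    r
  }, gene_sets, names(gene_sets), seeds)
  q <- stats::p.adjust(vapply(res, `[[`, 0, "p_value"), method = "BH")
  for (i in seq_along(res)) res[[i]]$fdr <- q[i]
  res
}

#' Gene set from peak-linked genes
#'
#' The unique nearest genes of a site set (e.g. the genes to which GLR
#' enhancer peaks map), optionally restricted to a biotype such as
#' `"protein_coding"`.
#'
#' @param sites data frame with `chrom` and `center`.
#' @param genes a [gene_table()].
#' @param biotype optional biotype filter applied to the linked genes.
#' @return character vector of unique gene ids.
#' @export
peak_gene_set <- function(sites, genes, biotype = NULL) {
  if (!nrow(sites)) return(character(0))
  linked <- link_to_genes(sites, genes)
  ids <- unique(linked$gene_id[!is.na(linked$gene_id)])
  if (!is.null(biotype))
    ids <- ids[genes$biotype[match(ids, genes$gene_id)] %in% biotype]
  sort(ids)
}

#' Expression change stratified by peak strength
#'
#' Compares log2 expression fold changes between genes nearest "stronger"
#' sites (pileup at or above the threshold, inclusive), genes nearest
#' only "weaker" sites, and all other expressed genes, by one-way ANOVA
#' with Tukey HSD post hoc comparisons.
#'
#' @param sites data frame with `chrom`, `center`, `pileup` (e.g. GLR
#'   sites anchored on the GFI1 peak).
#' @param expr an [expression_table()].
#' @param genes a [gene_table()].
#' @param pileup_threshold strength cut-off (default 35; `>=` is stronger).
#' @return list with `strata` (gene_id, stratum, log2fc), `comparison`
#'   (a [group_compare()] result) and `means` (per-stratum mean log2fc).
#' @export
strength_stratified_expression <- function(sites, expr, genes,
                                           pileup_threshold = 35) {
  stopifnot(inherits(expr, "ExpressionTable"))
  if (!all(c("chrom", "center", "pileup") %in% names(sites)))
    stop_input("sites must carry chrom, center and pileup columns")
  linked <- link_to_genes(sites, genes)
  strong_genes <- unique(linked$gene_id[linked$pileup >= pileup_threshold])
  weak_genes <- setdiff(unique(linked$gene_id[linked$pileup < pileup_threshold]),
                        strong_genes)
  strong_genes <- strong_genes[!is.na(strong_genes)]
  weak_genes <- weak_genes[!is.na(weak_genes)]
  e <- expr[expr$expressed, , drop = FALSE]
  stratum <- ifelse(e$gene_id %in% strong_genes, "stronger",
                    ifelse(e$gene_id %in% weak_genes, "weaker", "background"))
  for (s in c("stronger", "weaker", "background"))
    if (!any(stratum == s))
      stop_input("stratum '%s' is empty", s)
  strata <- data.frame(gene_id = e$gene_id, stratum = stratum,
                       log2fc = e$log2fc, stringsAsFactors = FALSE)
  groups <- split(strata$log2fc, strata$stratum)
  cmp <- group_compare(groups, method = "anova_tukey")
  list(strata = strata, comparison = cmp,
       means = vapply(groups, mean, 0))
}

#' Compare labelled value groups
#'
#' Standard group statistics used across the figure panels: pairwise
#' Welch t-tests, one-way ANOVA with Tukey HSD, or one-way ANOVA with
#' Fisher's LSD (unadjusted pooled-variance pairwise t-tests).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param method `"welch_t"`, `"anova_tukey"` or `"anova_fisher_lsd"`.
#' @param adjust optional p-adjustment (`"BH"`) applied across the
#'   reported pairwise comparisons.
#' @return list with `method`, `anova` (data.frame with F and p, `NULL`
#'   for `welch_t`) and `comparisons` (data.frame: group1, group2,
#'   estimate = mean difference, statistic where applicable, p_value,
#'   p_adjusted when `adjust` given).
#' @export
group_compare <- function(groups,
                          method = c("welch_t", "anova_tukey", "anova_fisher_lsd"),
                          adjust = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (length(groups) < 2) stop_input("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop_input("each group needs at least two values")
  labs <- names(groups)
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(labs, sizes), levels = labs)
  pair_idx <- utils::combn(seq_along(labs), 2)
  anova_tab <- NULL
  if (method == "welch_t") {
    comparisons <- do.call(rbind, apply(pair_idx, 2, function(ij) {
      a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group1 = labs[ij[1]], group2 = labs[ij[2]],
                 estimate = mean(a) - mean(b),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    }))
  } else {
    fit <- stats::aov(value ~ grp)
    s <- summary(fit)[[1]]
    anova_tab <- data.frame(F = s[["F value"]][1], p_value = s[["Pr(>F)"]][1])
    if (method == "anova_tukey") {
      tk <- stats::TukeyHSD(fit)$grp
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      comparisons <- data.frame(group1 = vapply(nm, `[`, "", 1),
                                group2 = vapply(nm, `[`, "", 2),
                                estimate = tk[, "diff"],
                                statistic = NA_real_,
                                p_value = tk[, "p adj"],
                                stringsAsFactors = FALSE)
      rownames(comparisons) <- NULL
    } else {
      pt <- stats::pairwise.t.test(value, grp, p.adjust.method = "none",
                                   pool.sd = TRUE)
      comparisons <- do.call(rbind, apply(pair_idx, 2, function(ij) {
        g1 <- labs[ij[1]]; g2 <- labs[ij[2]]
        p <- pt$p.value[g2, g1]
        if (is.na(p) && g1 %in% rownames(pt$p.value)) p <- pt$p.value[g1, g2]
        data.frame(group1 = g1, group2 = g2,
                   estimate = mean(groups[[ij[1]]]) - mean(groups[[ij[2]]]),
                   statistic = NA_real_, p_value = p,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  if (!is.null(adjust))
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, method = adjust)
  list(method = method, anova = anova_tab, comparisons = comparisons)
}
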