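ranked_fixture <- function(n, seed = 1) {
  withr::local_seed(seed, .local_envir = parent.frame())
  stats::setNames(sort(stats::rnorm(n), decreasing = TRUE),
                  sprintf("g%03d", sample.int(n)))
}

test_that("DE thresholding is inclusive and matches a direct filter", {
  ex <- expression_table(data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    expr_ctrl = 10, expr_trt = 10,
    log2fc = c(0.5, 0.49, -0.5, -0.51, 0),
    expressed = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  de <- select_de_genes(ex, 0.5)
  expect_equal(de$up, "a")          # exactly +0.5 is included
  expect_equal(de$down, c("c", "d"))
  expect_equal(de$n_expressed, 4)
  expect_length(intersect(de$up, de$down), 0)
  expect_error(select_de_genes(ex, 0), "positive")

  withr::local_seed(40)
  big <- expression_table(data.frame(
    gene_id = sprintf("g%03d", 1:200), expr_ctrl = 10, expr_trt = 10,
    log2fc = stats::rnorm(200, 0, 0.6)))
  de2 <- select_de_genes(big, 0.5)
  expect_setequal(de2$up, big$gene_id[big$log2fc >= 0.5])
  expect_setequal(de2$down, big$gene_id[big$log2fc <= -0.5])
  expect_lte(length(de2$up) + length(de2$down), de2$n_expressed)
})

test_that("unweighted ES equals the classical two-sample KS statistic", {
  withr::local_seed(50)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    v <- ranked_fixture(n, seed = sample.int(1e6, 1))
    k <- sample(seq(2, n - 2), 1)
    set <- sample(names(v), k)
    es <- enrichment_score(v, set, weight_exponent = 0)
    hits <- which(names(sort(v, decreasing = TRUE)) %in% set)
    hit_pos <- es$hit_positions
    miss_pos <- setdiff(seq_len(n), hit_pos)
    D <- suppressWarnings(stats::ks.test(hit_pos, miss_pos)$statistic)
    expect_equal(abs(es$es), unname(D), tolerance = 1e-12)
  }
})

test_that("ES sign and symmetry behave as a KS running sum should", {
  v <- stats::setNames(seq(10, 1), paste0("g", 1:10))
  bottom <- paste0("g", 8:10)
  expect_lt(enrichment_score(v, bottom, weight_exponent = 0)$es, 0)
  top <- paste0("g", 1:3)
  es_top <- enrichment_score(v, top, weight_exponent = 0)$es
  expect_gt(es_top, 0)
  # reversing the ranking negates the unweighted ES
  rev_v <- stats::setNames(rev(seq(10, 1)), paste0("g", 1:10))
  expect_equal(enrichment_score(rev_v, top, weight_exponent = 0)$es, -es_top)
  # leading edge of a clean top hit is the hit set itself
  expect_setequal(enrichment_score(v, top, weight_exponent = 0)$leading_edge,
                  top)
  expect_error(enrichment_score(v, character(0)), "non-empty")
  expect_error(enrichment_score(v, names(v)), "proper")
})

test_that("weighted ES agrees with an independent GSEA implementation", {
  withr::local_seed(66)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    v <- ranked_fixture(n, seed = sample.int(1e6, 1))
    set <- sample(names(v), sample(5:20, 1))
    mine <- enrichment_score(v, set, weight_exponent = 1)$es
    stats_sorted <- sort(v, decreasing = TRUE)
    ref <- fgsea::calcGseaStat(stats_sorted,
                               selectedStats = which(names(stats_sorted) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("the internal fast ES path equals the full running-sum path", {
  withr::local_seed(71)
  for (rep in 1:50) {
    n <- sample(20:300, 1)
    v <- ranked_fixture(n, seed = sample.int(1e6, 1))
    k <- sample(seq(2, min(n - 2, 40)), 1)
    pos <- sample.int(n, k)
    vv <- sort(v, decreasing = TRUE)
    full <- enrichment_score(vv, names(vv)[pos], weight_exponent = 1)$es
    fast <- glrscope:::es_from_positions(abs(vv)^1, n, pos)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("permutation NES is deterministic, seeded, and validated", {
  v <- ranked_fixture(200, seed = 9)
  set <- names(v)[c(1:10, 50, 120)]
  expect_error(normalized_enrichment(v, set, n_perm = 200), "seed")
  expect_warning(normalized_enrichment(v, set, n_perm = 50, seed = 1), "coarse")
  r1 <- normalized_enrichment(v, set, n_perm = 300, seed = 42)
  r2 <- normalized_enrichment(v, set, n_perm = 300, seed = 42)
  expect_identical(r1[c("es", "nes", "p_value")], r2[c("es", "nes", "p_value")])
  expect_lte(abs(r1$es), 1)
  expect_gte(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("permutation p-values control type-I error on null gene sets", {
  withr::local_seed(314)
  n <- 400
  p_vals <- vapply(1:50, function(i) {
    v <- stats::setNames(stats::rnorm(n), sprintf("g%03d", 1:n))
    set <- sample(names(v), 25)   # random set: the null is true
    normalized_enrichment(v, set, n_perm = 200,
                          seed = sample.int(1e6, 1))$p_value
  }, 0)
  # binomial 3-sigma bound on the 0.05 rejection rate over 50 draws
  expect_lte(mean(p_vals < 0.05), 0.12)
})

test_that("BH adjustment runs across multiple gene sets", {
  v <- ranked_fixture(150, seed = 10)
  sets <- list(top = names(v)[1:12],
               rand1 = sample(names(v), 12),
               rand2 = sample(names(v), 12))
  res <- run_enrichment(v, sets, n_perm = 200, seed = 5)
  expect_named(res, names(sets))
  p <- vapply(res, `[[`, 0, "p_value")
  q <- vapply(res, `[[`, 0, "fdr")
  expect_equal(unname(q), unname(stats::p.adjust(p, "BH")))
  expect_lt(res$top$p_value, 0.05)
})

test_that("group comparisons match closed-form statistics", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  w <- group_compare(g, "welch_t")
  expect_equal(w$comparisons$statistic, 0)
  expect_equal(w$comparisons$p_value, 1)

  three <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(group_compare(three, "anova_tukey")$anova$F, 0)

  ab <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  t_obs <- group_compare(ab, "welch_t")$comparisons$statistic
  # hand formula: means 2 and 5, each var 1, n 3 -> t = -3/sqrt(2/3)
  expect_equal(t_obs, -3 / sqrt(2 / 3))

  lsd <- group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(1, 3, 5)),
                       "anova_fisher_lsd", adjust = "BH")
  expect_equal(nrow(lsd$comparisons), 3)
  expect_true(all(lsd$comparisons$p_adjusted >= lsd$comparisons$p_value - 1e-12))
  expect_error(group_compare(list(a = 1, b = c(1, 2))), "at least two values")
  expect_error(group_compare(list(a = c(1, 2))), "two groups")
})

test_that("strength stratification is inclusive at the pileup threshold", {
  df <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "chr1",
                   strand = "+", start = seq(10000, 120000, by = 10000))
  df$end <- df$start + 1000
  genes <- toy_genes(df)
  sites <- data.frame(chrom = "chr1",
                      center = c(10010, 20010, 30010, 40010),
                      pileup = c(60, 35, 10, 12))
  withr::local_seed(2)
  expr <- expression_table(data.frame(
    gene_id = genes$gene_id, expr_ctrl = 10, expr_trt = 10,
    log2fc = c(1.2, 1.1, 0.05, 0.1, stats::rnorm(8, 0, 0.1))))
  out <- strength_stratified_expression(sites, expr, genes, 35)
  strata <- out$strata
  # pileup exactly 35 goes to the stronger stratum
  expect_setequal(strata$gene_id[strata$stratum == "stronger"], c("g01", "g02"))
  expect_setequal(strata$gene_id[strata$stratum == "weaker"], c("g03", "g04"))
  expect_equal(sum(strata$stratum == "background"), 8)
  expect_gt(out$means[["stronger"]], out$means[["weaker"]])
  expect_error(strength_stratified_expression(sites, expr, genes, 5), "empty")
})
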