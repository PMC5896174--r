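test_that("window RPKM implements the depth-integral definition", {
  trk <- flat_track(10, len = 10000, total = 1e6, read_length = 50)
  w <- genomic_interval("chr1", 4000, 5000)
  # depth 10 over 1000 bp / read length 50 -> 200 reads; RPKM = 200e9/(1e3*1e6)
  expect_equal(window_rpkm(trk, w), 200)
  # zero coverage
  z <- flat_track(0, len = 10000)
  expect_equal(window_rpkm(z, w), 0)
  # doubling the library size halves RPKM
  trk2 <- flat_track(10, len = 10000, total = 2e6, read_length = 50)
  expect_equal(window_rpkm(trk2, w), 100)
  expect_error(coverage_track(list(chr1 = rep(1, 10)), 0, 50), "positive")
})

test_that("RPKM counts are additive over window splits", {
  withr::local_seed(61)
  v <- stats::rpois(5000, 3) + stats::runif(5000)
  trk <- coverage_track(list(chr1 = v), total_mapped_reads = 1e6,
                        read_length = 50,
                        chrom_sizes = c(chr1 = 5000))
  full <- window_rpkm(trk, genomic_interval("chr1", 1000, 3000))
  halves <- window_rpkm(trk, data.frame(chrom = "chr1",
                                        start = c(1000, 2000),
                                        end = c(2000, 3000)))
  # counts add; each half has half the length, so RPKM of full = mean of halves
  expect_equal(full, mean(halves))
})

test_that("noise-free simulated tracks match the tent-kernel sum oracle", {
  cfg <- small_config(seed = 3, background_depth = 0, enhancer_fc_acetyl = 1.5)
  genome <- generate_genome(cfg)
  ps <- generate_peak_sets(cfg, genome)
  trk <- generate_coverage(cfg, genome, ps, marks = "H3K9Ac")[["H3K9Ac.DMSO"]]
  pk <- ps$peaks$H3K9Ac
  withr::local_seed(4)
  for (i in sample.int(nrow(pk), 10)) {
    ch <- pk$chrom[i]
    win_s <- pk$apex[i] - 1000; win_e <- pk$apex[i] + 1000
    sel <- pk$chrom == ch
    want_sum <- bf_tent_window_sum(pk$apex[sel], pk$pileup[sel], 300,
                                   win_s, win_e)
    got <- window_rpkm(trk, data.frame(chrom = ch, start = win_s, end = win_e))
    want <- (want_sum / trk$read_length) * 1e9 /
      (2000 * trk$total_mapped_reads)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("windows clip at chromosome ends and use the clipped length", {
  trk <- flat_track(4, len = 1000, total = 1e6, read_length = 50)
  # window [-500, 500) clips to [0, 500): 500 bp at depth 4
  got <- window_rpkm(trk, data.frame(chrom = "chr1", start = 0, end = 500))
  edge <- category_signal(trk, data.frame(chrom = "chr1", center = 0),
                          flank = 500)
  expect_equal(edge$rpkm, got)
  # beyond the declared chromosome size: [800, 1200) -> length 200
  over <- window_rpkm(trk, data.frame(chrom = "chr1", start = 800, end = 1200))
  expect_equal(over, (4 * 200 / 50) * 1e9 / (200 * 1e6))
})

test_that("meta-profiles: flat tracks, symmetry, permutation invariance", {
  trk <- flat_track(7, len = 50000)
  anchors <- data.frame(chrom = "chr1", pos = c(10000, 20000, 30000))
  mp <- meta_profile(trk, anchors, flank = 1000, bin_width = 25)
  expect_equal(nrow(mp), 2 * 1000 / 25)
  expect_equal(length(unique(round(mp$rpkm, 9))), 1)  # flat everywhere
  expect_error(meta_profile(trk, anchors[0, ], 1000, 25), "no anchors")
  expect_error(meta_profile(trk, anchors, 1000, 33), "divide")

  # symmetric flat block centered on the anchor -> exactly mirrored profile
  v <- rep(0, 20000); v[(10000 - 200 + 1):(10000 + 200)] <- 6
  bt <- coverage_track(list(chr1 = v), 1e6, 50, chrom_sizes = c(chr1 = 20000))
  prof <- meta_profile(bt, data.frame(chrom = "chr1", pos = 10000),
                       flank = 500, bin_width = 25)
  expect_equal(prof$rpkm, rev(prof$rpkm))

  # single tent kernel: every bin equals the per-base oracle sum
  vk <- glrscope:::add_tent_kernels(rep(0, 20000), 10000, 50, 300)
  kt <- coverage_track(list(chr1 = vk), 1e6, 50, chrom_sizes = c(chr1 = 20000))
  pk_prof <- meta_profile(kt, data.frame(chrom = "chr1", pos = 10000),
                          flank = 500, bin_width = 25)
  want <- vapply(pk_prof$offset, function(d)
    bf_tent_window_sum(10000, 50, 300, 10000 + d, 10000 + d + 25), 0)
  want <- (want / 50) * 1e9 / (25 * 1e6)
  expect_equal(pk_prof$rpkm, want, tolerance = 1e-10)

  perm <- meta_profile(trk, anchors[c(3, 1, 2), ], flank = 1000, bin_width = 25)
  expect_equal(mp$rpkm, perm$rpkm)
})

test_that("meta-profile is equivariant under coordinate translation", {
  withr::local_seed(9)
  v <- stats::rpois(30000, 2)
  shift <- 4000
  trk <- coverage_track(list(chr1 = v), 1e6, 50, chrom_sizes = c(chr1 = 30000))
  trk_shift <- coverage_track(list(chr1 = c(rep(0, shift), v)), 1e6, 50,
                              chrom_sizes = c(chr1 = 30000 + shift))
  anchors <- data.frame(chrom = "chr1", pos = c(8000, 15000, 22000))
  a2 <- data.frame(chrom = "chr1", pos = anchors$pos + shift)
  expect_equal(meta_profile(trk, anchors, 1000, 50)$rpkm,
               meta_profile(trk_shift, a2, 1000, 50)$rpkm)
})

test_that("heatmap matrices rank by strength and agree with the profile", {
  withr::local_seed(13)
  v <- stats::rpois(50000, 1) + stats::runif(50000)
  trk <- coverage_track(list(chr1 = v), 1e6, 50, chrom_sizes = c(chr1 = 50000))
  pk <- random_peak_set(12, chroms = "chr1", span = 40000)
  hm <- heatmap_matrix(trk, pk, flank = 1000, bin_width = 25)
  expect_equal(dim(hm), c(12, 80))
  expect_equal(rownames(hm),
               pk$peak_id[order(-pk$pileup, pk$chrom, pk$start)])
  mp <- meta_profile(trk, data.frame(chrom = pk$chrom, pos = pk$apex),
                     flank = 1000, bin_width = 25)
  expect_identical(unname(colMeans(hm, na.rm = TRUE)), mp$rpkm)
  # single peak: one row of 80 bins
  hm1 <- heatmap_matrix(trk, pk[1, , drop = FALSE], 1000, 25)
  expect_equal(dim(hm1), c(1, 80))
})

test_that("fold-change summaries behave on identities, scalings and planted effects", {
  trk <- flat_track(5, len = 20000)
  sites <- data.frame(chrom = "chr1", center = c(5000, 9000, 15000))
  same <- fold_change_summary(trk, trk, sites, flank = 1000)
  expect_equal(same$percent_change, 0)
  expect_equal(same$per_site$log2fc, rep(0, 3))

  dbl <- flat_track(10, len = 20000)
  up <- fold_change_summary(trk, dbl, sites, flank = 1000, pseudocount = 1e-9)
  expect_equal(up$percent_change, 100)
  expect_equal(up$per_site$log2fc, rep(1, 3), tolerance = 1e-6)

  zero <- flat_track(0, len = 20000)
  expect_error(fold_change_summary(zero, trk, sites, 1000), "zero")

  # noise-free planted 1.5x at GLR sites only
  cfg <- small_config(seed = 101, background_depth = 0,
                      enhancer_fc_acetyl = 1.5)
  genome <- generate_genome(cfg)
  ps <- generate_peak_sets(cfg, genome)
  tr <- generate_coverage(cfg, genome, ps, marks = "H3K9Ac")
  man <- ps$manifest$sites
  glr <- man[man$triple & man$marked, , drop = FALSE]
  fc <- fold_change_summary(tr[["H3K9Ac.DMSO"]], tr[["H3K9Ac.OG86"]],
                            data.frame(chrom = glr$chrom, center = glr$apex),
                            flank = 1000)
  expect_equal(fc$percent_change, 50, tolerance = 1e-6)
  other <- man[!man$triple & man$marked, , drop = FALSE]
  fc0 <- fold_change_summary(tr[["H3K9Ac.DMSO"]], tr[["H3K9Ac.OG86"]],
                             data.frame(chrom = other$chrom,
                                        center = other$apex), flank = 1000)
  expect_equal(fc0$percent_change, 0, tolerance = 1e-6)
})
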