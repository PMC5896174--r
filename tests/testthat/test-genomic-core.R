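test_that("narrowPeak parsing follows the format conventions", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t500\tp1\t0\t.\t8.0\t-1\t-1\t150",
               "chr1\t600\t800\tp2\t0\t.\t3.5\t-1\t-1\t-1"), f)
  ps <- read_peaks(f, "narrowPeak")
  expect_equal(nrow(ps), 2)
  expect_equal(ps$start[1], 100)
  expect_equal(ps$end[1], 500)
  expect_equal(ps$apex[1], 100 + 150)
  expect_equal(ps$pileup[1], 8.0)
  # missing summit (-1) falls back to the floored interval midpoint
  expect_equal(ps$apex[2], (600 + 800) %/% 2)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(read_peaks(empty, "narrowPeak")), 0)

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t100\t500\tp1\t0\t.\t8.0\t-1\t-1\t150",
               "chr1\t1\t2\tp2"), bad)
  expect_error(read_peaks(bad, "narrowPeak"), "line 2")

  outside <- withr::local_tempfile()
  writeLines("chr1\t100\t500\tp1\t0\t.\t8.0\t-1\t-1\t900", outside)
  expect_error(read_peaks(outside, "narrowPeak"), "outside")
})

test_that("MACS2 peak tables are converted from 1-based coordinates", {
  f <- withr::local_tempfile(fileext = ".xls")
  writeLines(c("# MACS2 output",
               paste("chr", "start", "end", "length", "abs_summit", "pileup",
                     "-log10(pvalue)", "fold_enrichment", "-log10(qvalue)",
                     "name", sep = "\t"),
               paste("chr2", "1001", "2000", "1000", "1500", "42.5",
                     "30.1", "8.8", "25.2", "m1", sep = "\t")), f)
  ps <- read_peaks(f, "macs2_xls")
  expect_equal(ps$start, 1000)   # 1-based inclusive -> 0-based half-open
  expect_equal(ps$end, 2000)
  expect_equal(ps$apex, 1499)
  expect_equal(ps$pileup, 42.5)
  expect_equal(ps$peak_id, "m1")
})

test_that("peak sets round-trip through narrowPeak and keep sorted order", {
  withr::local_seed(11)
  ps <- random_peak_set(50)
  f <- withr::local_tempfile()
  write_peaks(ps, f)
  back <- read_peaks(f, "narrowPeak")
  expect_equal(as.data.frame(back), as.data.frame(ps))
  expect_true(!is.unsorted(order(ps$chrom, ps$start)))
  # optional pileup floor drops weak peaks
  floored <- read_peaks(f, "narrowPeak", min_pileup = 50)
  expect_true(all(floored$pileup >= 50))
})

test_that("bedGraph coverage reads, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t100\t5.0", f)
  trk <- read_coverage(f, total_mapped_reads = 1e6, read_length = 50)
  # depth 5 on [0,100), 0 elsewhere; mean over [50,150) = 2.5
  s <- glrscope:::depth_window_sums(trk, "chr1", 50, 150)
  expect_equal(s / 100, 2.5)
  expect_equal(glrscope:::depth_window_sums(trk, "chr1", 200, 300), 0)
  expect_equal(glrscope:::depth_window_sums(trk, "chrX", 0, 100), 0)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  etrk <- read_coverage(empty, 1e6, 50)
  expect_equal(glrscope:::depth_window_sums(etrk, "chr1", 0, 1000), 0)

  neg <- withr::local_tempfile()
  writeLines("chr1\t0\t100\t-1", neg)
  expect_error(read_coverage(neg, 1e6, 50), "negative")

  ovl <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), ovl)
  expect_error(read_coverage(ovl, 1e6, 50), "overlap")

  # round trip with gaps
  f2 <- withr::local_tempfile()
  writeLines(c("chr1\t10\t20\t3", "chr1\t40\t60\t1.5", "chr2\t0\t5\t2"), f2)
  t2 <- read_coverage(f2, 1e6, 50)
  f3 <- withr::local_tempfile()
  write_coverage(t2, f3)
  t3 <- read_coverage(f3, 1e6, 50)
  for (ch in c("chr1", "chr2"))
    expect_equal(as.numeric(t2$depths[[ch]]), as.numeric(t3$depths[[ch]]))
})

test_that("gene models read from GTF with coordinate conversion and validation", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA"; gene_name "A"; gene_biotype "protein_coding";',
    'chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t1801\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tgene_id "gB"; gene_biotype "lncRNA";',
    'chr1\tsrc\texon\t5001\t6000\t.\t-\t.\tgene_id "gB";'), gtf)
  g <- read_genes(gtf, "gtf")
  expect_equal(g$start[g$gene_id == "gA"], 1000)  # 1-based -> 0-based
  expect_equal(g$end[g$gene_id == "gA"], 2000)
  expect_equal(g$tss[g$gene_id == "gA"], 1000)
  # minus-strand TSS is end - 1
  expect_equal(g$tss[g$gene_id == "gB"], 5999)
  expect_equal(g$biotype[g$gene_id == "gB"], "lncRNA")
  expect_equal(nrow(g$exons[[which(g$gene_id == "gA")]]), 2)

  noexon <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t3001\t4000\t.\t+\t.\tgene_id "gC";'), noexon)
  expect_error(read_genes(noexon, "gtf"), "zero exons")

  dup <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    'chr2\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA";'), dup)
  expect_error(read_genes(dup, "gtf"), "duplicate")
})

test_that("gene models round-trip through GTF and read from BED12", {
  withr::local_seed(5)
  sim <- simulate_dataset(small_config(), coverage = FALSE)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_genes(sim$genes, f)
  back <- read_genes(f, "gtf")
  expect_equal(back$gene_id, sim$genes$gene_id)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
  expect_equal(back$tss, sim$genes$tss)
  expect_equal(back$strand, sim$genes$strand)
  expect_equal(back$biotype, sim$genes$biotype)
  for (i in seq_len(nrow(back)))
    expect_equal(back$exons[[i]], sim$genes$exons[[i]],
                 ignore_attr = TRUE)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", "1000", "3000", "gX", "0", "-", "1000", "3000",
                   "0", "2", "200,300", "0,1700", sep = "\t"), bed)
  gb <- read_genes(bed, "bed12")
  expect_equal(gb$start, 1000)
  expect_equal(gb$tss, 2999)
  expect_equal(gb$exons[[1]]$start, c(1000, 2700))
  expect_equal(gb$exons[[1]]$end, c(1200, 3000))
})

test_that("interval distance: overlap, gap, chromosomes, metric properties", {
  a <- genomic_interval("chr1", 100, 200)
  expect_equal(interval_distance(a, genomic_interval("chr1", 150, 300)), 0)
  expect_equal(interval_distance(a, genomic_interval("chr1", 205, 300)), 5)
  expect_equal(interval_distance(a, genomic_interval("chr2", 100, 200)), Inf)
  withr::local_seed(31)
  for (i in 1:50) {
    s <- sort(sample.int(1000, 6))
    x <- genomic_interval("chr1", s[1], s[2])
    y <- genomic_interval("chr1", s[3], s[4])
    z <- genomic_interval("chr1", s[5], s[6])
    expect_equal(interval_distance(x, y), interval_distance(y, x))
    # triangle-style relation for co-chromosomal intervals
    expect_lte(interval_distance(x, z),
               interval_distance(x, y) + interval_distance(y, z) +
                 (y$end - y$start))
  }
})

test_that("nearest_tss honours conventions and matches brute force", {
  g <- toy_genes(data.frame(gene_id = c("a", "b", "c"),
                            chrom = "chr1", strand = c("+", "+", "-"),
                            start = c(1000, 5000, 9000),
                            end = c(2000, 6000, 10000)))
  # query at a TSS
  hit <- nearest_tss("chr1", 5000, g)
  expect_equal(hit$gene_id, "b")
  expect_equal(hit$distance, 0)
  # equidistant between b's TSS (5000) and c's TSS (9999) at 7499.5 -> use
  # integer midpoint ties: genes at TSS 100 and 300, query 200
  g2 <- toy_genes(data.frame(gene_id = c("zz", "aa"), chrom = "chr1",
                             strand = "+", start = c(100, 300),
                             end = c(200, 400)))
  expect_equal(nearest_tss("chr1", 200, g2)$gene_id, "aa")
  expect_error(nearest_tss("chr2", 100, g), "no gene")

  withr::local_seed(17)
  df <- data.frame(gene_id = sprintf("g%03d", 1:40),
                   chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                   strand = sample(c("+", "-"), 40, replace = TRUE),
                   start = sample.int(100000, 40))
  df$end <- df$start + sample(500:2000, 40, replace = TRUE)
  genes <- toy_genes(df)
  pos <- sample.int(110000, 1000, replace = TRUE)
  chrom <- sample(c("chr1", "chr2"), 1000, replace = TRUE)
  got <- nearest_tss(chrom, pos, genes)
  for (k in sample.int(1000, 200)) {
    sub <- genes[genes$chrom == chrom[k], ]
    d <- abs(sub$tss - pos[k])
    best <- min(d)
    cand <- sort(sub$gene_id[d == best])[1]
    expect_equal(got$gene_id[k], cand)
    expect_equal(got$abs_distance[k], best)
  }
})

test_that("expression tables validate, round-trip, and apply floors", {
  df <- data.frame(gene_id = c("a", "b", "c"),
                   expr_ctrl = c(10, 0.1, 100), expr_trt = c(20, 0.1, 50),
                   log2fc = c(1, 0, -1))
  ex <- expression_table(df, min_expr = 1)
  expect_equal(ex$expressed, c(TRUE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ex, f)
  expect_equal(as.data.frame(read_expression(f)), as.data.frame(ex))
  expect_error(expression_table(rbind(df, df[1, ])), "duplicate")

  sets <- list(up_targets = c("a", "c"), other = "b")
  sf <- withr::local_tempfile()
  write_gene_sets(sets, sf)
  expect_equal(read_gene_sets(sf)[names(sets)], sets)
})
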