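# Independent brute-force oracles and small fixture builders.

# all-pairs coincidence: for each query apex, the nearest target apex on the
# same chromosome if |delta| <= window (inclusive), ties to the smaller
# coordinate. O(n*m), no sorting tricks.
bf_nearest_partner <- function(queries, targets, window) {
  res <- data.frame(peak_id = queries$peak_id, partner_id = NA_character_,
                    apex_distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(queries))) {
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(nrow(targets))) {
      if (queries$chrom[i] != targets$chrom[j]) next
      d <- abs(queries$apex[i] - targets$apex[j])
      if (d > window) next
      if (d < bestd || (d == bestd && !is.na(best) &&
                        targets$apex[j] < targets$apex[best])) {
        best <- j; bestd <- d
      }
    }
    if (!is.na(best)) {
      res$partner_id[i] <- targets$peak_id[best]
      res$apex_distance[i] <- bestd
    }
  }
  res
}

# greedy one-to-one matching by ascending apex distance (same rule as the
# partition), written as an explicit pair enumeration + loop
bf_greedy_claim <- function(anchors, partners, window) {
  pairs <- NULL
  for (i in seq_len(nrow(anchors))) for (j in seq_len(nrow(partners))) {
    if (anchors$chrom[i] != partners$chrom[j]) next
    d <- abs(anchors$apex[i] - partners$apex[j])
    if (d <= window)
      pairs <- rbind(pairs, data.frame(i = i, j = j, d = d,
                                       chrom = anchors$chrom[i],
                                       aa = anchors$apex[i],
                                       pa = partners$apex[j]))
  }
  out <- rep(NA_character_, nrow(anchors))
  if (is.null(pairs)) return(out)
  pairs <- pairs[order(pairs$d, pairs$chrom, pairs$aa, pairs$pa), , drop = FALSE]
  a_used <- rep(FALSE, nrow(anchors)); p_used <- rep(FALSE, nrow(partners))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (a_used[i] || p_used[j]) next
    a_used[i] <- TRUE; p_used[j] <- TRUE
    out[i] <- partners$peak_id[j]
  }
  out
}

# full category partition using the brute-force greedy matcher
bf_partition_counts <- function(gfi1, lsd1, rcor1, window) {
  gl <- bf_greedy_claim(gfi1, lsd1, window)
  gr <- bf_greedy_claim(gfi1, rcor1, window)
  g_cat <- ifelse(!is.na(gl) & !is.na(gr), "GLR",
                  ifelse(!is.na(gl), "GL", ifelse(!is.na(gr), "GR", "G")))
  l_rest <- lsd1[!(lsd1$peak_id %in% gl), , drop = FALSE]
  r_rest <- rcor1[!(rcor1$peak_id %in% gr), , drop = FALSE]
  lr <- if (nrow(l_rest) && nrow(r_rest))
    bf_greedy_claim(l_rest, r_rest, window) else rep(NA_character_, nrow(l_rest))
  l_cat <- ifelse(!is.na(lr), "LR", "L")
  n_r_single <- nrow(r_rest) - sum(!is.na(lr))
  tab <- table(c(g_cat, l_cat, rep("R", n_r_single)))
  as.list(tab)
}

# per-base depth sum of a tent kernel track over a window, by explicit
# evaluation (independent of the Rle/Views machinery)
bf_tent_window_sum <- function(apexes, heights, halfwidth, start, end) {
  if (end <= start) return(0)
  x <- start:(end - 1)
  s <- 0
  for (i in seq_along(apexes)) {
    contrib <- heights[i] * (1 - abs(x - apexes[i]) / halfwidth)
    s <- s + sum(contrib[abs(x - apexes[i]) < halfwidth])
  }
  s
}

# random peak set fixture
random_peak_set <- function(n, chroms = c("chr1", "chr2"), span = 100000,
                            prefix = "p", factor = NA_character_) {
  if (n == 0)
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric(), apex = numeric(),
                               pileup = numeric(), peak_id = character()),
                    factor = factor))
  chrom <- sample(chroms, n, replace = TRUE)
  apex <- sample.int(span, n)
  w <- sample(100:400, n, replace = TRUE)
  start <- pmax(apex - w %/% 2, 0)
  peak_set(data.frame(chrom = chrom, start = start, end = start + w,
                      apex = apex, pileup = stats::runif(n, 1, 100),
                      peak_id = sprintf("%s%04d", prefix, seq_len(n))),
           factor = factor)
}

# tiny deterministic gene fixture: one gene per row spec
toy_genes <- function(df) {
  df$exons <- lapply(seq_len(nrow(df)), function(i)
    data.frame(start = df$start[i], end = df$end[i]))
  gene_table(df)
}

# constant-depth coverage track fixture
flat_track <- function(depth, len = 10000, chrom = "chr1",
                       total = 1e6, read_length = 50) {
  coverage_track(stats::setNames(list(rep(depth, len)), chrom),
                 total_mapped_reads = total, read_length = read_length,
                 chrom_sizes = stats::setNames(len, chrom))
}
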