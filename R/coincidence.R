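#' Peak co-occupancy by apex distance
#'
#' Two peaks are "coincident" when their apexes (summits) lie within a
#' fixed window of each other on the same chromosome — the rule used to
#' call co-binding of GFI1 with LSD1/RCOR1. The boundary is inclusive:
#' an apex separation exactly equal to the window counts as coincident.
#' Strand plays no role.
#'
#' `find_partners()` is the vectorised workhorse: for each query peak it
#' returns the target peak with the minimal `|apex difference|` within the
#' window (ties broken toward the smaller target coordinate), or `NA`.
#'
#' @param queries,targets [peak_set()] objects.
#' @param window maximum apex separation in bp (default 500).
#' @return data.frame with one row per query: `peak_id`, `partner_id`,
#'   `apex_distance` (`NA` when no target apex falls within the window).
#' @export
find_partners <- function(queries, targets, window = 500) {
  stopifnot(inherits(queries, "PeakSet"), inherits(targets, "PeakSet"))
  if (window <= 0) stop_input("window must be positive")
  out <- data.frame(peak_id = queries$peak_id,
                    partner_id = NA_character_,
                    apex_distance = NA_real_)
  for (ch in unique(queries$chrom)) {
    qsel <- which(queries$chrom == ch)
    t <- targets[targets$chrom == ch, , drop = FALSE]
    if (nrow(t) == 0) next
    ord <- order(t$apex, t$start, t$peak_id, method = "radix")
    ta <- t$apex[ord]; tid <- t$peak_id[ord]
    qa <- queries$apex[qsel]
    idx <- findInterval(qa, ta)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(ta))
    dlo <- abs(qa - ta[lo]); dhi <- abs(qa - ta[hi])
    # tie toward the smaller coordinate = the left candidate
    use_hi <- dhi < dlo
    pick <- ifelse(use_hi, hi, lo)
    d <- pmin(dlo, dhi)
    ok <- d <= window
    out$partner_id[qsel[ok]] <- tid[pick[ok]]
    out$apex_distance[qsel[ok]] <- d[ok]
  }
  out
}

#' @rdname find_partners
#' @param query a single-row [peak_set()] (or one row of one).
#' @return `is_coincident()`: the partner peak as a one-row data frame, or
#'   `NULL` when no target lies within the window.
#' @export
is_coincident <- function(query, targets, window = 500) {
  if (nrow(query) != 1) stop_input("is_coincident expects a single query peak")
  if (!inherits(query, "PeakSet"))
    query <- peak_set(query)
  hit <- find_partners(query, targets, window)
  if (is.na(hit$partner_id[1])) return(NULL)
  p <- as.data.frame(targets)[targets$peak_id == hit$partner_id[1], , drop = FALSE]
  p$apex_distance <- hit$apex_distance[1]
  rownames(p) <- NULL
  p
}

#' Coincidence summary between two peak sets
#'
#' The number and percentage of query peaks with at least one target apex
#' within the window — the statistic behind statements like "71.3% of
#' GFI1 peaks were coincident with an LSD1 peak". The percentage is
#' reported to one decimal place (rounded half-up).
#'
#' @inheritParams find_partners
#' @return one-row data.frame: `query_factor`, `target_factor`, `n_query`,
#'   `n_coincident`, `fraction`, `percent`.
#' @export
coincidence_summary <- function(queries, targets, window = 500) {
  if (nrow(queries) == 0)
    stop_input("coincidence_summary: empty query set (fraction undefined)")
  hits <- find_partners(queries, targets, window)
  n <- nrow(queries)
  k <- sum(!is.na(hits$partner_id))
  data.frame(query_factor = attr(queries, "factor") %||% NA_character_,
             target_factor = attr(targets, "factor") %||% NA_character_,
             n_query = n, n_coincident = k,
             fraction = k / n,
             percent = percent_of(k, n, digits = 1))
}

#' Coincidence among the strongest peaks
#'
#' [coincidence_summary()] restricted to the strongest `fraction` of the
#' query set by pileup (e.g. the strongest 5% of GFI1 peaks).
#'
#' @inheritParams find_partners
#' @param fraction strongest fraction of queries to keep, in (0, 1].
#' @export
stratified_coincidence <- function(queries, targets, window = 500,
                                   fraction = 0.05) {
  coincidence_summary(top_fraction(queries, fraction), targets, window)
}

#' Partition three peak sets into co-occupancy categories
#'
#' Classifies every input peak into exactly one Venn-style site:
#' GFI1 peaks are the anchors for the categories containing G
#' (`GLR`, `GL`, `GR`, `G`), with LSD1 and RCOR1 partners claimed
#' one-to-one, greedily by ascending apex distance, within the window of
#' the GFI1 apex (no mutual L-R constraint at GLR sites). LSD1 and RCOR1
#' peaks left unclaimed then form `LR` sites when mutually within the
#' window (again greedy one-to-one), and `L` / `R` singleton sites
#' otherwise. Every peak contributes to exactly one site and no partner
#' is claimed twice.
#'
#' Site coordinates, apex and pileup are those of the anchor peak
#' (the GFI1 peak for G-containing categories, the LSD1 peak for LR/L,
#' the RCOR1 peak for R).
#'
#' @param gfi1,lsd1,rcor1 [peak_set()] objects with globally unique ids.
#' @param window apex window in bp (default 500, inclusive).
#' @return a `CategoryAssignment` data.frame: `site_id`, `category`,
#'   `chrom`, `start`, `end`, `apex`, `pileup`, `gfi1_id`, `lsd1_id`,
#'   `rcor1_id` (NA where that factor is absent from the category).
#' @export
partition_categories <- function(gfi1, lsd1, rcor1, window = 500) {
  stopifnot(inherits(gfi1, "PeakSet"), inherits(lsd1, "PeakSet"),
            inherits(rcor1, "PeakSet"))
  ids <- c(gfi1$peak_id, lsd1$peak_id, rcor1$peak_id)
  if (anyDuplicated(ids))
    stop_input("duplicate peak id '%s' across input sets",
               ids[duplicated(ids)][1])
  gl <- greedy_claim(gfi1, lsd1, window)
  gr <- greedy_claim(gfi1, rcor1, window)
  has_l <- !is.na(gl$partner_id)
  has_r <- !is.na(gr$partner_id)
  g_cat <- ifelse(has_l & has_r, "GLR",
                  ifelse(has_l, "GL", ifelse(has_r, "GR", "G")))
  g_sites <- data.frame(site_id = gfi1$peak_id, category = g_cat,
                        chrom = gfi1$chrom, start = gfi1$start,
                        end = gfi1$end, apex = gfi1$apex,
                        pileup = gfi1$pileup,
                        gfi1_id = gfi1$peak_id,
                        lsd1_id = gl$partner_id, rcor1_id = gr$partner_id,
                        stringsAsFactors = FALSE)
  l_rest <- peak_subset(lsd1, !(lsd1$peak_id %in% gl$partner_id))
  r_rest <- peak_subset(rcor1, !(rcor1$peak_id %in% gr$partner_id))
  lr_sites <- l_sites <- r_sites <- NULL
  if (nrow(l_rest) && nrow(r_rest)) {
    lr <- greedy_claim(l_rest, r_rest, window)
  } else {
    lr <- data.frame(peak_id = l_rest$peak_id,
                     partner_id = rep(NA_character_, nrow(l_rest)))
  }
  if (nrow(l_rest)) {
    paired <- !is.na(lr$partner_id)
    l_sites <- data.frame(site_id = l_rest$peak_id,
                          category = ifelse(paired, "LR", "L"),
                          chrom = l_rest$chrom, start = l_rest$start,
                          end = l_rest$end, apex = l_rest$apex,
                          pileup = l_rest$pileup,
                          gfi1_id = NA_character_,
                          lsd1_id = l_rest$peak_id,
                          rcor1_id = lr$partner_id,
                          stringsAsFactors = FALSE)
  }
  r_single <- peak_subset(r_rest, !(r_rest$peak_id %in% lr$partner_id))
  if (nrow(r_single)) {
    r_sites <- data.frame(site_id = r_single$peak_id, category = "R",
                          chrom = r_single$chrom, start = r_single$start,
                          end = r_single$end, apex = r_single$apex,
                          pileup = r_single$pileup,
                          gfi1_id = NA_character_, lsd1_id = NA_character_,
                          rcor1_id = r_single$peak_id,
                          stringsAsFactors = FALSE)
  }
  out <- rbind(g_sites, l_sites, r_sites)
  out <- out[genomic_order(out$chrom, out$start, out$end, out$site_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("CategoryAssignment", "data.frame"))
}

peak_subset <- function(peaks, keep) {
  df <- as.data.frame(peaks)[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, factor = attr(peaks, "factor"),
            condition = attr(peaks, "condition"),
            class = c("PeakSet", "data.frame"))
}

# One-to-one greedy matching of anchors to partners by ascending apex
# distance; deterministic tie-break by (distance, anchor chrom, anchor apex,
# partner apex). Returns one row per anchor with the claimed partner (or NA).
greedy_claim <- function(anchors, partners, window) {
  res <- data.frame(peak_id = anchors$peak_id, partner_id = NA_character_,
                    apex_distance = NA_real_, stringsAsFactors = FALSE)
  pairs <- candidate_pairs(anchors, partners, window)
  if (!nrow(pairs)) return(res)
  pairs <- pairs[order(pairs$dist, pairs$chrom, pairs$a_apex, pairs$p_apex,
                       method = "radix"), , drop = FALSE]
  a_taken <- new.env(parent = emptyenv())
  p_taken <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a_id[i]; p <- pairs$p_id[i]
    if (!is.null(a_taken[[a]]) || !is.null(p_taken[[p]])) next
    a_taken[[a]] <- p; p_taken[[p]] <- a
    j <- match(a, res$peak_id)
    res$partner_id[j] <- p
    res$apex_distance[j] <- pairs$dist[i]
  }
  res
}

# all (anchor, partner) pairs with |apex difference| <= window, same chrom
candidate_pairs <- function(anchors, partners, window) {
  out <- list()
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    p <- partners[partners$chrom == ch, , drop = FALSE]
    if (!nrow(p)) next
    ord <- order(p$apex, p$peak_id, method = "radix")
    pa <- p$apex[ord]; pid <- p$peak_id[ord]
    lo <- findInterval(a$apex - window - 0.5, pa) + 1L
    hi <- findInterval(a$apex + window + 0.5, pa)
    n_each <- pmax(hi - lo + 1L, 0L)
    if (!sum(n_each)) next
    ai <- rep(seq_len(nrow(a)), n_each)
    pj <- unlist(lapply(seq_len(nrow(a)), function(i)
      if (n_each[i] > 0) seq(lo[i], hi[i]) else integer(0)))
    out[[ch]] <- data.frame(chrom = ch,
                            a_id = a$peak_id[ai], p_id = pid[pj],
                            a_apex = a$apex[ai], p_apex = pa[pj],
                            dist = abs(a$apex[ai] - pa[pj]),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), a_id = character(),
                      p_id = character(), a_apex = numeric(),
                      p_apex = numeric(), dist = numeric()))
  do.call(rbind, out)
}

#' Category partition report
#'
#' Tabulates category counts with percentages. For standard Venn labels
#' (subsets of the letters G, L, R) it also reports each category as a
#' percentage of that factor's total peaks (e.g. the share of all
#' GFI1-containing sites that are GLR). Percentages are rounded half-up
#' to `digits` decimals, matching the printed-precision convention of
#' figures such as "23% (1,556/6,778)".
#'
#' @param assignments a [partition_categories()] result, or any data frame
#'   with a `category` column.
#' @param digits decimal places for percentages (default 0).
#' @return list with `table` (category, count, pct_of_sites and, where
#'   applicable, pct_of_G/pct_of_L/pct_of_R) and `totals` (named counts:
#'   sites plus per-factor peak totals).
#' @export
partition_report <- function(assignments, digits = 0) {
  if (!"category" %in% names(assignments))
    stop_input("assignments must carry a 'category' column")
  counts <- table(assignments$category)
  cats <- names(counts)
  n_sites <- sum(counts)
  tab <- data.frame(category = cats, count = as.integer(counts),
                    pct_of_sites = percent_of(as.integer(counts), n_sites, digits),
                    stringsAsFactors = FALSE)
  totals <- c(sites = n_sites)
  for (f in c("G", "L", "R")) {
    has_f <- grepl(f, cats, fixed = TRUE)
    if (!any(has_f)) next
    f_total <- sum(counts[has_f])
    totals[f] <- f_total
    col <- rep(NA_real_, length(cats))
    col[has_f] <- percent_of(as.integer(counts[has_f]), f_total, digits)
    tab[[paste0("pct_of_", f)]] <- col
  }
  list(table = tab, totals = totals)
}
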