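#' Call active intergenic enhancers
#'
#' An active intergenic enhancer is a region at least `min_gene_distance`
#' (default 5 kb) from any annotated gene locus that carries coincident
#' H3K9Ac and H3K4Me2 peaks. "Coincident" is interpreted as interval
#' overlap between the two mark peaks (broad histone peaks have unstable
#' summits); an apex-distance mode is available via `mark_coincidence`.
#' Each candidate is an H3K9Ac peak overlapping at least one H3K4Me2
#' peak; its region is the union of the overlapping intervals and its
#' center the H3K9Ac apex. Retained regions that overlap each other are
#' merged, keeping the apex of the strongest contributing H3K9Ac peak as
#' the center.
#'
#' @param h3k9ac,h3k4me2 [peak_set()] objects for the two marks.
#' @param genes a [gene_table()]; distance is measured to the transcript
#'   locus, not only the TSS.
#' @param min_gene_distance minimum bp gap to the nearest gene (default 5000).
#' @param lsd1 optional LSD1 [peak_set()]; when given, each enhancer is
#'   flagged `lsd1_bound` if an LSD1 apex lies within `window` bp of its
#'   center.
#' @param window apex window used for the `lsd1_bound` flag (default 500).
#' @param mark_coincidence `"overlap"` (default) or `"apex"`; in apex mode
#'   the marks must have apexes within `apex_window` bp.
#' @param apex_window window for `mark_coincidence = "apex"`.
#' @return data.frame of enhancer regions: `enhancer_id`, `chrom`,
#'   `start`, `end`, `center`, `pileup` (H3K9Ac strength at the center),
#'   `h3k9ac_ids`, `h3k4me2_ids` (comma-separated), `nearest_gene_id`,
#'   `distance_to_gene`, and `lsd1_bound` when `lsd1` was supplied.
#' @export
call_active_enhancers <- function(h3k9ac, h3k4me2, genes,
                                  min_gene_distance = 5000,
                                  lsd1 = NULL, window = 500,
                                  mark_coincidence = c("overlap", "apex"),
                                  apex_window = 500) {
  stopifnot(inherits(h3k9ac, "PeakSet"), inherits(h3k4me2, "PeakSet"),
            inherits(genes, "GeneTable"))
  mark_coincidence <- match.arg(mark_coincidence)
  empty <- data.frame(enhancer_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), center = numeric(),
                      pileup = numeric(), h3k9ac_ids = character(),
                      h3k4me2_ids = character(),
                      nearest_gene_id = character(),
                      distance_to_gene = numeric())
  if (!nrow(h3k9ac) || !nrow(h3k4me2)) return(empty)
  levs <- union(unique(h3k9ac$chrom), unique(h3k4me2$chrom))
  qr <- GenomicRanges::GRanges(factor(h3k9ac$chrom, levels = levs),
                               IRanges::IRanges(h3k9ac$start + 1, h3k9ac$end))
  sr <- GenomicRanges::GRanges(factor(h3k4me2$chrom, levels = levs),
                               IRanges::IRanges(h3k4me2$start + 1, h3k4me2$end))
  if (mark_coincidence == "overlap") {
    ov <- GenomicRanges::findOverlaps(qr, sr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  } else {
    hits <- find_partners(h3k9ac, h3k4me2, apex_window)
    qh <- which(!is.na(hits$partner_id))
    sh <- match(hits$partner_id[qh], h3k4me2$peak_id)
  }
  if (!length(qh)) return(empty)
  cand_idx <- sort(unique(qh))
  cand <- data.frame(
    chrom = h3k9ac$chrom[cand_idx],
    start = vapply(cand_idx, function(i)
      min(h3k9ac$start[i], h3k4me2$start[sh[qh == i]]), 0),
    end = vapply(cand_idx, function(i)
      max(h3k9ac$end[i], h3k4me2$end[sh[qh == i]]), 0),
    center = h3k9ac$apex[cand_idx],
    pileup = h3k9ac$pileup[cand_idx],
    h3k9ac_id = h3k9ac$peak_id[cand_idx],
    h3k4me2_ids = vapply(cand_idx, function(i)
      paste(sort(h3k4me2$peak_id[sh[qh == i]]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  # distance filter against gene loci
  gene_iv <- data.frame(chrom = genes$chrom, start = genes$start,
                        end = genes$end)
  d <- interval_to_set_distance(cand, gene_iv)
  cand <- cand[d >= min_gene_distance, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # merge overlapping retained candidates; center = strongest H3K9Ac apex
  cr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1, cand$end))
  red <- GenomicRanges::reduce(cr)
  grp <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(cr, red))
  merged <- lapply(split(seq_len(nrow(cand)), grp), function(idx) {
    best <- idx[order(-cand$pileup[idx], cand$start[idx])][1]
    data.frame(chrom = cand$chrom[best],
               start = min(cand$start[idx]), end = max(cand$end[idx]),
               center = cand$center[best], pileup = cand$pileup[best],
               h3k9ac_ids = paste(sort(unique(cand$h3k9ac_id[idx])), collapse = ","),
               h3k4me2_ids = paste(sort(unique(unlist(
                 strsplit(cand$h3k4me2_ids[idx], ",")))), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[genomic_order(out$chrom, out$start, out$end), , drop = FALSE]
  out$enhancer_id <- sprintf("enh_%05d", seq_len(nrow(out)))
  ng <- nearest_tss(out$chrom, out$center, genes, error_on_missing = FALSE)
  out$nearest_gene_id <- ng$gene_id
  out$distance_to_gene <- interval_to_set_distance(out, gene_iv)
  if (!is.null(lsd1)) {
    centers <- peak_set(data.frame(chrom = out$chrom, start = out$start,
                                   end = out$end, apex = out$center,
                                   pileup = out$pileup,
                                   peak_id = out$enhancer_id))
    hits <- find_partners(centers, lsd1, window)
    out$lsd1_bound <- !is.na(hits$partner_id[match(out$enhancer_id,
                                                   hits$peak_id)])
  }
  rownames(out) <- NULL
  front <- c("enhancer_id", "chrom", "start", "end", "center", "pileup")
  out[c(front, setdiff(names(out), front))]
}

#' Annotate peak genomic locations
#'
#' Assigns each peak one location class by its apex with the precedence
#' promoter > exonic > intronic > intergenic: promoter when the apex is
#' within `promoter_halfwidth` bp of any TSS (inclusive), exonic when it
#' falls inside an exon, intronic when inside a gene locus but not an
#' exon, intergenic otherwise.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_table()].
#' @param promoter_halfwidth promoter half-width in bp around the TSS
#'   (default 1000).
#' @return data.frame: `peak_id`, `class`, `gene_id` (the promoter's gene,
#'   or the enclosing gene for exonic/intronic; `NA` for intergenic).
#' @export
annotate_location <- function(peaks, genes, promoter_halfwidth = 1000) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(genes, "GeneTable"))
  n <- nrow(peaks)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)
  if (!n) return(data.frame(peak_id = character(), class = character(),
                            gene_id = character()))
  if (nrow(genes)) {
    # promoter: apex within halfwidth of a TSS
    nt <- nearest_tss(peaks$chrom, peaks$apex, genes, error_on_missing = FALSE,
                      warn = FALSE)
    prom <- !is.na(nt$abs_distance) & nt$abs_distance <= promoter_halfwidth
    # exon / locus membership via interval overlap (shared seqlevels so
    # peak-only chromosomes do not trip findOverlaps)
    levs <- union(unique(peaks$chrom), unique(genes$chrom))
    apex_gr <- GenomicRanges::GRanges(
      factor(peaks$chrom, levels = levs),
      IRanges::IRanges(peaks$apex + 1, width = 1))
    ex <- data.frame(
      chrom = rep(genes$chrom, vapply(genes$exons, nrow, 0L)),
      gene_id = rep(genes$gene_id, vapply(genes$exons, nrow, 0L)),
      do.call(rbind, genes$exons))
    ex_gr <- GenomicRanges::GRanges(factor(ex$chrom, levels = levs),
                                    IRanges::IRanges(ex$start + 1, ex$end))
    loc_gr <- GenomicRanges::GRanges(factor(genes$chrom, levels = levs),
                                     IRanges::IRanges(genes$start + 1, genes$end))
    ov_ex <- GenomicRanges::findOverlaps(apex_gr, ex_gr, select = "first")
    ov_loc <- GenomicRanges::findOverlaps(apex_gr, loc_gr, select = "first")
    in_ex <- !is.na(ov_ex)
    in_loc <- !is.na(ov_loc)
    cls[in_loc] <- "intronic"
    gid[in_loc] <- genes$gene_id[ov_loc[in_loc]]
    cls[in_ex] <- "exonic"
    gid[in_ex] <- ex$gene_id[ov_ex[in_ex]]
    cls[prom] <- "promoter"
    gid[prom] <- nt$gene_id[prom]
  }
  data.frame(peak_id = peaks$peak_id, class = cls, gene_id = gid,
             stringsAsFactors = FALSE)
}

#' Flag genes with a peak at the promoter
#'
#' A gene is "bound" when some peak apex lies within `halfwidth` bp of
#' its TSS (boundary inclusive) — e.g. promoters with versus without an
#' LSD1 peak within 1 kb of the TSS.
#'
#' @param genes a [gene_table()].
#' @param peaks a [peak_set()].
#' @param halfwidth promoter half-width in bp (default 1000).
#' @return data.frame: `gene_id`, `bound` (logical).
#' @export
promoter_bound_genes <- function(genes, peaks, halfwidth = 1000) {
  stopifnot(inherits(genes, "GeneTable"), inherits(peaks, "PeakSet"))
  bound <- rep(FALSE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gsel <- which(genes$chrom == ch)
    apexes <- sort(peaks$apex[peaks$chrom == ch])
    if (!length(apexes)) next
    tss <- genes$tss[gsel]
    lo <- findInterval(tss - halfwidth - 0.5, apexes) + 1L
    hi <- findInterval(tss + halfwidth + 0.5, apexes)
    bound[gsel] <- hi >= lo
  }
  data.frame(gene_id = genes$gene_id, bound = bound, stringsAsFactors = FALSE)
}

#' Link sites to their nearest gene
#'
#' Assigns each site (any table with `chrom` and `center`) to the gene
#' with the TSS nearest the site center; many sites may share one gene.
#' Ties go to the lexicographically smaller `gene_id`. Sites on a
#' chromosome with no genes are flagged unassigned with a warning.
#'
#' @param sites data frame with `chrom` and `center` columns (and
#'   optionally an id column, preserved).
#' @param genes a [gene_table()].
#' @return `sites` with added `gene_id`, `tss_distance` (signed,
#'   center - TSS) columns.
#' @export
link_to_genes <- function(sites, genes) {
  if (!all(c("chrom", "center") %in% names(sites)))
    stop_input("sites must carry chrom and center columns")
  nt <- nearest_tss(sites$chrom, sites$center, genes, error_on_missing = FALSE)
  sites$gene_id <- nt$gene_id
  sites$tss_distance <- nt$distance
  sites
}
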