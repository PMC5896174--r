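#' Windowed RPKM signal
#'
#' Normalised signal (reads per kilobase per million mapped reads) over
#' fixed genomic windows. The estimated read count in a window is the
#' per-base depth integral divided by the read length; RPKM is then
#' `count * 1e9 / (window_length * total_mapped_reads)`. Windows are
#' clipped at chromosome ends and the clipped length is used in the
#' denominator; a window clipped to zero length yields `NA`.
#'
#' @param track a [coverage_track()].
#' @param windows data frame with `chrom`, `start`, `end` (0-based
#'   half-open), or a single window given as `chrom`/`start`/`end`
#'   scalars via [genomic_interval()].
#' @return numeric vector of RPKM values, one per window.
#' @export
window_rpkm <- function(track, windows) {
  stopifnot(inherits(track, "CoverageTrack"))
  validate_intervals(windows, "window")
  if (track$total_mapped_reads <= 0)
    stop_input("total_mapped_reads must be positive")
  cl <- clip_windows(track, windows$chrom, windows$start, windows$end)
  len <- cl$end - cl$start
  sums <- depth_window_sums(track, cl$chrom, cl$start, cl$end)
  counts <- sums / track$read_length
  rpkm <- counts * 1e9 / (len * track$total_mapped_reads)
  rpkm[len <= 0] <- NA_real_
  rpkm
}

#' Signal at site centers
#'
#' One RPKM value per site over `center ± flank` — the per-site
#' quantification behind category box plots (± 1 kb) and promoter/
#' enhancer fold changes (± 2.5 kb).
#'
#' @param track a [coverage_track()].
#' @param sites data frame with `chrom` and `center` (plus any id columns,
#'   preserved in the result).
#' @param flank half-width of the window in bp.
#' @return `sites` with an added `rpkm` column.
#' @export
category_signal <- function(track, sites, flank) {
  if (!all(c("chrom", "center") %in% names(sites)))
    stop_input("sites must carry chrom and center columns")
  if (flank <= 0) stop_input("flank must be positive")
  win <- data.frame(chrom = sites$chrom,
                    start = sites$center - flank,
                    end = sites$center + flank)
  win$start <- pmax(win$start, 0)  # validated clip; RPKM clips again vs sizes
  sites$rpkm <- window_rpkm(track, win)
  sites
}

#' Condition fold change at a site set
#'
#' Per-site log2 fold change of RPKM between a treated and control track
#' (with a pseudocount guarding zero-signal sites), and the summary
#' percent change `100 * (mean_trt / mean_ctrl - 1)` computed on the
#' unshifted per-site means — the estimator behind statements like
#' "mean ChIP-seq signal increased by 48%".
#'
#' @param track_ctrl,track_trt [coverage_track()] objects on the same
#'   normalisation basis (same library-size convention).
#' @param sites data frame with `chrom` and `center`.
#' @param flank window half-width in bp (default 1000).
#' @param pseudocount RPKM pseudocount for per-site log2fc (default 0.5).
#' @return list with `per_site` (sites plus `rpkm_ctrl`, `rpkm_trt`,
#'   `log2fc`), `mean_ctrl`, `mean_trt`, `percent_change`.
#' @export
fold_change_summary <- function(track_ctrl, track_trt, sites, flank = 1000,
                                pseudocount = 0.5) {
  ctrl <- category_signal(track_ctrl, sites, flank)$rpkm
  trt <- category_signal(track_trt, sites, flank)$rpkm
  per_site <- sites
  per_site$rpkm_ctrl <- ctrl
  per_site$rpkm_trt <- trt
  per_site$log2fc <- log2((trt + pseudocount) / (ctrl + pseudocount))
  m_ctrl <- mean(ctrl, na.rm = TRUE)
  m_trt <- mean(trt, na.rm = TRUE)
  if (!is.finite(m_ctrl) || m_ctrl == 0)
    stop_input("fold_change_summary: control mean signal is zero; percent change undefined")
  list(per_site = per_site, mean_ctrl = m_ctrl, mean_trt = m_trt,
       percent_change = 100 * (m_trt / m_ctrl - 1))
}

# per-site x per-bin RPKM matrix over anchor +/- flank; shared by
# meta_profile and heatmap_matrix so their consistency is structural
signal_matrix <- function(track, chrom, pos, flank, bin_width) {
  if (flank <= 0 || bin_width <= 0) stop_input("flank and bin_width must be positive")
  if ((2 * flank) %% bin_width != 0)
    stop_input("bin_width must divide 2*flank")
  offsets <- seq(-flank, flank - bin_width, by = bin_width)
  n <- length(pos); b <- length(offsets)
  win <- data.frame(chrom = rep(chrom, times = b),
                    start = rep(pos, times = b) + rep(offsets, each = n),
                    end = rep(pos, times = b) + rep(offsets, each = n) + bin_width)
  keep_neg <- win$end > 0
  win$start <- pmax(win$start, 0)
  win$end <- pmax(win$end, win$start + 1)  # placeholder for fully-left bins
  vals <- window_rpkm(track, win)
  vals[!keep_neg] <- NA_real_
  m <- matrix(vals, nrow = n, ncol = b)
  colnames(m) <- offsets
  m
}

#' Meta-profile around anchor positions
#'
#' Mean RPKM per offset bin across a set of anchor positions (e.g. mean
#' ChIP signal surrounding peak apexes). Bins that fall off a chromosome
#' end are clipped; anchors whose bin is entirely outside are excluded
#' from that bin's mean.
#'
#' @param track a [coverage_track()].
#' @param anchors data frame with `chrom` and `pos` (anchor bp positions,
#'   typically peak apexes).
#' @param flank profile half-width in bp.
#' @param bin_width bin width in bp; must divide `2 * flank`.
#' @return data.frame with `offset` (bin start relative to the anchor)
#'   and `rpkm` (mean over anchors), `2 * flank / bin_width` rows.
#' @export
meta_profile <- function(track, anchors, flank, bin_width) {
  if (!all(c("chrom", "pos") %in% names(anchors)))
    stop_input("anchors must carry chrom and pos columns")
  if (!nrow(anchors)) stop_input("meta_profile: no anchors")
  m <- signal_matrix(track, anchors$chrom, anchors$pos, flank, bin_width)
  data.frame(offset = as.numeric(colnames(m)),
             rpkm = colMeans(m, na.rm = TRUE))
}

#' Strength-ranked heatmap matrix
#'
#' Per-peak binned RPKM over `apex ± flank`, rows ordered by pileup
#' descending (ties by chrom then start) — the matrix behind
#' strength-ranked ChIP signal heatmaps. Column means of the matrix equal
#' the corresponding [meta_profile()] values.
#'
#' @param track a [coverage_track()].
#' @param peaks a [peak_set()] (rows are ranked by its `pileup`).
#' @param flank half-width in bp (default 1000).
#' @param bin_width bin width in bp (default 25).
#' @return numeric matrix (peaks x bins) with `dimnames` = peak ids and
#'   bin offsets, ordered strongest first.
#' @export
heatmap_matrix <- function(track, peaks, flank = 1000, bin_width = 25) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (!nrow(peaks)) stop_input("heatmap_matrix: no peaks")
  ord <- order(-peaks$pileup, peaks$chrom, peaks$start, method = "radix")
  p <- peaks[ord, , drop = FALSE]
  m <- signal_matrix(track, p$chrom, p$apex, flank, bin_width)
  rownames(m) <- p$peak_id
  m
}
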