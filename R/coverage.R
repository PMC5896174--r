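#' Construct a coverage track
#'
#' A per-base read-depth step function for one mark/factor in one
#' condition, stored as run-length-encoded vectors per chromosome, plus
#' the library-size normaliser (`total_mapped_reads`) and the read length
#' used to convert summed depth back into read counts. Positions beyond
#' the covered range read as depth 0.
#'
#' @param depths named list of numeric vectors or [S4Vectors::Rle] objects,
#'   one per chromosome, all values `>= 0`.
#' @param total_mapped_reads positive count used as the per-million scaler.
#' @param read_length read length in bp (depth integral / read_length =
#'   estimated read count).
#' @param mark,condition labels.
#' @param chrom_sizes optional named vector of chromosome lengths; windows
#'   are clipped to these when computing RPKM denominators.
#' @return a `CoverageTrack` object.
#' @export
coverage_track <- function(depths, total_mapped_reads, read_length,
                           mark = NA_character_, condition = NA_character_,
                           chrom_sizes = NULL) {
  stopifnot(is.list(depths))
  if (length(depths) && is.null(names(depths)))
    stop_input("coverage depths must be a named (per-chromosome) list")
  depths <- lapply(depths, function(v) {
    r <- if (inherits(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    if (length(r) && min(S4Vectors::runValue(r)) < 0)
      stop_input("coverage depth must be non-negative")
    r
  })
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0)
    stop_input("total_mapped_reads must be a positive number")
  if (!is.numeric(read_length) || read_length <= 0)
    stop_input("read_length must be a positive number")
  structure(list(depths = depths,
                 total_mapped_reads = as.numeric(total_mapped_reads),
                 read_length = as.numeric(read_length),
                 mark = mark, condition = condition,
                 chrom_sizes = chrom_sizes),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: mark=%s condition=%s, %d chromosome(s), %s reads (read length %g)\n",
              x$mark, x$condition, length(x$depths),
              format(x$total_mapped_reads, big.mark = ","), x$read_length))
  invisible(x)
}

#' Read a coverage track from bedGraph
#'
#' Intervals must be 0-based half-open with non-negative values and must
#' not overlap; gaps read back as depth 0.
#'
#' @param path bedGraph file path.
#' @param total_mapped_reads,read_length library normaliser and read
#'   length (bedGraph does not carry them).
#' @param mark,condition,chrom_sizes see [coverage_track()].
#' @return a [coverage_track()].
#' @export
read_coverage <- function(path, total_mapped_reads, read_length,
                          mark = NA_character_, condition = NA_character_,
                          chrom_sizes = NULL) {
  if (!file.exists(path)) stop_input("coverage file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    if (min(S4Vectors::mcols(gr)$score) < 0)
      stop_input("%s: negative coverage value", path)
    red <- GenomicRanges::reduce(gr)
    if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(gr)))
      stop_input("%s: overlapping bedGraph intervals", path)
  }
  depths <- list()
  if (length(gr)) {
    cov <- GenomicRanges::coverage(gr, weight = S4Vectors::mcols(gr)$score)
    depths <- as.list(cov)
  }
  coverage_track(depths, total_mapped_reads, read_length,
                 mark = mark, condition = condition, chrom_sizes = chrom_sizes)
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted (they are implicit in bedGraph).
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$depths)) {
    r <- track$depths[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)  # 0-based starts
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(starts[keep]),
                       as.integer(ends[keep]), sprintf("%.10g", vals[keep])), con)
  }
  invisible(path)
}

# Sum of per-base depth over 0-based half-open windows (vectorised).
# Windows are intersected with the covered range; everything outside is 0.
depth_window_sums <- function(track, chrom, start, end) {
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    r <- track$depths[[ch]]
    if (is.null(r) || length(r) == 0) next
    s <- pmax(start[sel] + 1, 1)
    e <- pmin(end[sel], length(r))
    ok <- s <= e
    if (!any(ok)) next
    v <- IRanges::Views(r, start = s[ok], end = e[ok])
    out[sel[ok]] <- IRanges::viewSums(v)
  }
  out
}

# Clip windows to [0, chrom_size) when sizes are known; always clip at 0.
clip_windows <- function(track, chrom, start, end) {
  start <- pmax(start, 0)
  if (!is.null(track$chrom_sizes)) {
    sz <- track$chrom_sizes[chrom]
    end <- ifelse(is.na(sz), end, pmin(end, sz))
  }
  data.frame(chrom = chrom, start = start, end = end)
}
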