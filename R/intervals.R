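#' Genomic intervals
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval covers bases `start, ..., end - 1`. 1-based formats (GTF,
#' MACS2 peak tables) are converted at the file boundary. A genomic interval
#' is represented as a data frame with columns `chrom`, `start`, `end`
#' (and optionally `strand`); most functions accept any data frame carrying
#' those columns.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, 0-based exclusive ends.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"`.
#' @return a data.frame with validated interval columns.
#' @export
#' @examples
#' genomic_interval("chr1", 100, 500)
genomic_interval <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = strand,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop_input("%s table must have chrom/start/end columns", what)
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop_input("%s has empty chromosome name", what)
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop_input("%s %d violates 0 <= start < end (start=%s, end=%s)",
               what, bad[1], df$start[bad[1]], df$end[bad[1]])
  invisible(df)
}

#' Distance between two genomic intervals
#'
#' Gap in bp between two 0-based half-open intervals: 0 when they overlap
#' or abut is the gap; `Inf` when the intervals lie on different chromosomes.
#' Overlapping intervals have distance 0. Strand is ignored.
#'
#' @param a,b data frames with `chrom`, `start`, `end`; either a single row
#'   or equal numbers of rows (compared element-wise).
#' @return numeric vector of distances in bp (`Inf` across chromosomes).
#' @export
#' @examples
#' interval_distance(genomic_interval("chr1", 100, 200),
#'                   genomic_interval("chr1", 205, 300))  # 5
interval_distance <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(b$start[bi] - a$end[ai], a$start[ai] - b$end[bi], 0)
  gap[a$chrom[ai] != b$chrom[bi]] <- Inf
  gap
}

# interval-set to interval-set minimal gap per query row (Inf if the query's
# chromosome is absent from the subject set). Points are width-1 intervals.
interval_to_set_distance <- function(query, subject) {
  validate_intervals(query); validate_intervals(subject)
  out <- rep(Inf, nrow(query))
  for (ch in unique(query$chrom)) {
    qsel <- which(query$chrom == ch)
    sub <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    qr <- IRanges::IRanges(start = query$start[qsel] + 1L, end = query$end[qsel])
    sr <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::distanceToNearest(qr, sr)
    out[qsel][S4Vectors::queryHits(hits)] <- as.numeric(S4Vectors::mcols(hits)$distance)
  }
  out
}

# distance from points (chrom,pos 0-based) to the nearest interval in `ivs`
point_to_interval_distance <- function(chrom, pos, ivs) {
  interval_to_set_distance(
    data.frame(chrom = chrom, start = pos, end = pos + 1), ivs)
}
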