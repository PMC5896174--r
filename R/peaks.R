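#' Construct a peak set
#'
#' A `PeakSet` is a data frame of called binding peaks for one factor (or
#' histone mark) in one condition, sorted by `(chrom, start)`. Each peak
#' carries its summit ("apex", the base of maximal read pileup) and a
#' non-negative strength (`pileup`, the MACS2 pileup value or the
#' narrowPeak signal value).
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `apex`,
#'   `pileup`, `peak_id` (0-based half-open coordinates; `apex` absolute bp).
#' @param factor label of the immunoprecipitated protein or mark.
#' @param condition condition label (e.g. `"DMSO"`, `"OG86"`).
#' @return a `PeakSet` (data.frame subclass), sorted by `(chrom, start)`.
#' @export
peak_set <- function(df, factor = NA_character_, condition = NA_character_) {
  req <- c("chrom", "start", "end", "apex", "pileup", "peak_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_input("peak table missing columns: %s",
                               paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$chrom <- as.character(df$chrom)
  df$peak_id <- as.character(df$peak_id)
  validate_intervals(df, "peak")
  bad <- which(!(df$apex >= df$start & df$apex < df$end))
  if (length(bad))
    stop_input("peak '%s': summit %s outside interval [%s,%s)",
               df$peak_id[bad[1]], df$apex[bad[1]], df$start[bad[1]], df$end[bad[1]])
  if (any(df$pileup < 0)) stop_input("pileup must be non-negative")
  if (anyDuplicated(df$peak_id))
    stop_input("duplicate peak_id '%s'", df$peak_id[duplicated(df$peak_id)][1])
  df <- df[genomic_order(df$chrom, df$start, df$end, df$peak_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, factor = factor, condition = condition,
            class = c("PeakSet", "data.frame"))
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peaks, factor=%s, condition=%s\n",
              nrow(x), attr(x, "factor") %||% NA, attr(x, "condition") %||% NA))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read called peaks from a MACS2-style file
#'
#' Supports ENCODE narrowPeak (BED6+4, 0-based half-open; the summit is
#' column 10 as an offset from `start`, with `-1` meaning "no summit
#' called") and the MACS2 tab-separated peak table (`*_peaks.xls`;
#' 1-based inclusive coordinates with `abs_summit` and `pileup` columns,
#' converted to 0-based half-open on read). For narrowPeak, the
#' `signalValue` column (7) is used as the peak strength since narrowPeak
#' has no pileup field. A missing summit falls back to the interval
#' midpoint (floor).
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"macs2_xls"`.
#' @param factor,condition labels attached to the returned set.
#' @param min_pileup optional strength floor; peaks below it are dropped
#'   (no filter by default — the MACS2 threshold already applied upstream).
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, format = c("narrowPeak", "macs2_xls"),
                       factor = NA_character_, condition = NA_character_,
                       min_pileup = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("peak file not found: %s", path)
  df <- switch(format,
               narrowPeak = parse_narrowpeak(path),
               macs2_xls = parse_macs2_xls(path))
  if (!is.null(min_pileup)) df <- df[df$pileup >= min_pileup, , drop = FALSE]
  peak_set(df, factor = factor, condition = condition)
}

parse_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      apex = numeric(), pileup = numeric(), peak_id = character()))
  fields <- strsplit(lines, "\t| +")
  n <- lengths(fields)
  bad <- which(n != 10L)
  if (length(bad))
    stop_input("%s: line %d is not a 10-column narrowPeak record (%d fields)",
               path, bad[1], n[bad[1]])
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  signal <- suppressWarnings(as.numeric(m[, 7]))
  summit <- suppressWarnings(as.numeric(m[, 10]))
  bad <- which(is.na(start) | is.na(end) | is.na(signal) | is.na(summit))
  if (length(bad))
    stop_input("%s: line %d has non-numeric coordinate/signal/summit fields",
               path, bad[1])
  apex <- ifelse(summit >= 0, start + summit, (start + end) %/% 2)
  data.frame(chrom = m[, 1], start = start, end = end, apex = apex,
             pileup = signal, peak_id = m[, 4], stringsAsFactors = FALSE)
}

parse_macs2_xls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) < 1L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      apex = numeric(), pileup = numeric(), peak_id = character()))
  header <- strsplit(lines[1], "\t")[[1]]
  req <- c("chr", "start", "end", "abs_summit", "pileup", "name")
  if (!all(req %in% header))
    stop_input("%s: MACS2 table header lacks columns: %s", path,
               paste(setdiff(req, header), collapse = ", "))
  body <- lines[-1]
  if (!length(body))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      apex = numeric(), pileup = numeric(), peak_id = character()))
  fields <- strsplit(body, "\t")
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop_input("%s: line %d has %d fields, header has %d", path, bad[1] + 1L,
               lengths(fields)[bad[1]], length(header))
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  start1 <- suppressWarnings(as.numeric(m[, "start"]))
  end1 <- suppressWarnings(as.numeric(m[, "end"]))
  summit1 <- suppressWarnings(as.numeric(m[, "abs_summit"]))
  pileup <- suppressWarnings(as.numeric(m[, "pileup"]))
  bad <- which(is.na(start1) | is.na(end1) | is.na(summit1) | is.na(pileup))
  if (length(bad))
    stop_input("%s: line %d has non-numeric fields", path, bad[1] + 1L)
  # 1-based inclusive -> 0-based half-open; abs_summit is a 1-based position
  data.frame(chrom = m[, "chr"], start = start1 - 1, end = end1,
             apex = summit1 - 1, pileup = pileup, peak_id = m[, "name"],
             stringsAsFactors = FALSE)
}

#' Write a peak set as narrowPeak
#'
#' Emits BED6+4: `signalValue` carries the pileup, column 10 the summit
#' offset from `start`. `read_peaks()` on the output reproduces the input.
#'
#' @param peaks a [peak_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   peaks$peak_id, sprintf("%.10g", peaks$pileup),
                   as.integer(peaks$apex - peaks$start))
  writeLines(lines, path)
  invisible(path)
}

#' Strongest fraction of a peak set
#'
#' The top `ceil(fraction * n)` peaks by pileup, e.g. the "strongest 5%"
#' stratum used when relating peak strength to co-occupancy. Ties in pileup
#' are broken by `(chrom, start)` so the selection is deterministic.
#'
#' @param peaks a [peak_set()] (non-empty).
#' @param fraction in (0, 1].
#' @return a [peak_set()] with `ceiling(fraction * nrow(peaks))` peaks.
#' @export
top_fraction <- function(peaks, fraction) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (nrow(peaks) == 0) stop_input("top_fraction: empty peak set")
  if (!(fraction > 0 && fraction <= 1))
    stop_input("fraction must be in (0, 1]")
  k <- ceiling(fraction * nrow(peaks))
  ord <- order(-peaks$pileup, peaks$chrom, peaks$start, method = "radix")
  peak_set(as.data.frame(peaks)[ord[seq_len(k)], , drop = FALSE],
           factor = attr(peaks, "factor"), condition = attr(peaks, "condition"))
}
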