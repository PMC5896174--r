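#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero
#' for positive input), matching the convention used when reporting
#' percentages such as "71.3%". Base R's `round()` rounds halves to even,
#' which would occasionally disagree at the printed precision.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(22.956, 1)  # 23.0
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param n count (numeric vector).
#' @param total denominator (must be > 0).
#' @param digits decimal places (0 or 1 in the standard reports).
#' @return numeric percentage(s).
#' @export
#' @examples
#' percent_of(214, 766)       # 28
#' percent_of(1556, 6778)     # 23
percent_of <- function(n, total, digits = 0) {
  stopifnot(is.numeric(n), is.numeric(total))
  if (any(total <= 0)) stop("percentage denominator must be positive")
  round_half_up(100 * n / total, digits)
}

# Derive independent per-stage seeds from one master seed. Kept below 2^31 so
# they are valid R integer seeds.
derive_seeds <- function(seed, n, label = "stage") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent ordering used for all peak-like tables
genomic_order <- function(chrom, start, end = NULL, id = NULL) {
  if (is.null(end)) end <- start
  if (is.null(id)) id <- seq_along(chrom)
  order(chrom, start, end, id, method = "radix")
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
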