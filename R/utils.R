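#' Round half-up at a fixed number of decimal places
#'
#' Summary tables in this package round half-away-from-zero at the printed
#' precision (so 146.375 -> 146.38), unlike [base::round()], which rounds
#' half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(146.375, 2) # 146.38
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Express a count ratio as a percentage
#'
#' The rounding rule used for every reported count ratio: percentage,
#' rounded half-up at `digits` decimal places.
#'
#' @param numerator,denominator non-negative numbers; `denominator > 0`.
#' @param digits decimal places (default 1).
#' @return percentage as a plain number (e.g. 69.3 for 79/114).
#' @examples
#' fraction_pct(79, 114) # 69.3
#' @export
fraction_pct <- function(numerator, denominator, digits = 1) {
  stopifnot(denominator > 0, numerator >= 0)
  round_half_up(100 * numerator / denominator, digits)
}

# Validate a BED-like data.frame (0-based half-open intervals).
# Returns the frame with chrom as character, sorted if sort = TRUE.
check_intervals <- function(x, what = "interval table", sort = FALSE,
                            required = c("chrom", "start", "end")) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0 && ncol(x) == 0)) {
    x <- data.frame(chrom = character(), start = numeric(), end = numeric())
    for (cn in setdiff(required, names(x))) x[[cn]] <- character()
  }
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop(sprintf("%s lacks column(s): %s", what,
                 paste(missing_cols, collapse = ", ")))
  }
  x$chrom <- as.character(x$chrom)
  bad <- which(!(x$start < x$end) | x$start < 0)
  if (length(bad)) {
    stop(sprintf("%s: malformed interval in record %d (%s:%s-%s)",
                 what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (sort) x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# BED-like data.frame -> GRanges (0-based half-open -> 1-based closed).
as_granges0 <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

# GRanges -> BED-like data.frame.
as_bed0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

# Child seeds derived from one shared seed by fixed offsets, so adding a
# feature class does not perturb the draws of another. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

empty_bed <- function(...) {
  extra <- list(...)
  base <- data.frame(chrom = character(), start = numeric(), end = numeric())
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}
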