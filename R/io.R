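#' Read a BED file into a 0-based half-open interval table
#'
#' Columns beyond the third are kept; column 4 is named `name`, column 6
#' `strand`, following BED conventions.
#'
#' @param path path to a tab-separated BED file without header.
#' @return data.frame with columns `chrom`, `start`, `end` and any extras.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- c(nm[seq_len(min(ncol(x), 6))],
                if (ncol(x) > 6) paste0("V", 7:ncol(x)))
  check_intervals(x, what = basename(path))
}

#' Write a BED-like interval table
#'
#' @param x data.frame with `chrom`, `start`, `end` first (extra columns are
#'   written after them, in their current order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  first <- c("chrom", "start", "end")
  x <- x[, c(first, setdiff(names(x), first)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-CpG methylation track
#'
#' Native dialect: 5 tab-separated columns, no header --
#' chrom, start, end, coverage, fraction_methylated (fraction in \[0,1\]).
#' Positions are the C of each CG on the forward strand, 0-based half-open.
#'
#' @param path path to the TSV.
#' @return a methylation track data.frame, sorted by chrom then position.
#' @seealso [read_bedmethyl()] for the 9+-column bedMethyl format.
#' @export
read_methylation <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(ncol(x) >= 5)
  x <- x[, 1:5]
  names(x) <- c("chrom", "start", "end", "coverage", "fraction")
  validate_track(x)
}

#' Read a bedMethyl-style file
#'
#' Accepts the 9+-column bedMethyl layout in which column 10 is the valid
#' coverage and column 11 the percent methylated; percent is mapped to a
#' fraction in \[0,1\].
#'
#' @param path path to the bedMethyl file.
#' @return a methylation track data.frame (chrom, start, end, coverage,
#'   fraction).
#' @export
read_bedmethyl <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 11) stop("bedMethyl input needs >= 11 columns")
  out <- data.frame(chrom = as.character(x[[1]]), start = x[[2]], end = x[[3]],
                    coverage = x[[10]], fraction = x[[11]] / 100)
  validate_track(out)
}

#' Write a methylation track in the native 5-column dialect
#'
#' @param track methylation track data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "coverage", "fraction")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_track <- function(x) {
  x <- check_intervals(x, what = "methylation track", sort = TRUE)
  if (any(x$fraction < 0 | x$fraction > 1)) {
    stop("methylation fractions must lie in [0, 1]")
  }
  dup <- duplicated(x[, c("chrom", "start")])
  if (any(dup)) x <- x[!dup, , drop = FALSE]
  rownames(x) <- NULL
  x
}
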