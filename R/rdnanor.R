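# rDNA/NOR accounting: copy number per array by span division, NOR status
# per chromosome, and per-haplotype/diploid totals.

#' Estimate rDNA unit copy number from array span
#'
#' Copy number = span / unit length, rounded half-up to an integer. Span 0
#' (no array) gives 0.
#'
#' @param array_span_bp array span in bp (>= 0).
#' @param unit_length_bp rDNA unit length in bp (> 0; human unit ~45 kb).
#' @return integer copy number.
#' @examples
#' count_rdna_units(913000, 45000) # 20
#' @export
count_rdna_units <- function(array_span_bp, unit_length_bp = 45000) {
  stopifnot(unit_length_bp > 0)
  if (any(array_span_bp < 0)) stop("negative rDNA array span")
  as.integer(round_half_up(array_span_bp / unit_length_bp))
}

#' Classify a chromosome as NOR-bearing (NOR+) or not (NOR-)
#'
#' NOR+ iff the chromosome carries an rDNA-class array with at least
#' `min_units` estimated copies. A single-unit array counts by default.
#'
#' @param chrom_arrays classified arrays of one chromosome (columns
#'   `class`, `start`, `end`).
#' @param unit_length_bp rDNA unit length (default 45000).
#' @param min_units minimal copy number for NOR+ (default 1).
#' @return `"NOR+"` or `"NOR-"`.
#' @export
classify_nor <- function(chrom_arrays, unit_length_bp = 45000, min_units = 1) {
  rd <- chrom_arrays[chrom_arrays$class == "rdna", , drop = FALSE]
  if (nrow(rd)) {
    units <- count_rdna_units(rd$end - rd$start, unit_length_bp)
    if (any(units >= min_units)) return("NOR+")
  }
  "NOR-"
}

#' Total rDNA copy numbers per haplotype or diploid
#'
#' @param arrays data.frame with `haplotype` and `copies` columns (one row
#'   per rDNA array).
#' @param group_by `"haplotype"` (totals per haplotype label) or
#'   `"diploid"` (single total over both haplotypes).
#' @return data.frame of totals (`haplotype`/`group`, `total_copies`);
#'   a zero total for an empty input.
#' @export
total_rdna <- function(arrays, group_by = c("haplotype", "diploid")) {
  group_by <- match.arg(group_by)
  if (is.null(arrays) || !nrow(arrays)) {
    return(if (group_by == "diploid") {
      data.frame(group = "diploid", total_copies = 0)
    } else {
      data.frame(haplotype = character(), total_copies = numeric())
    })
  }
  stopifnot(all(c("haplotype", "copies") %in% names(arrays)))
  if (group_by == "diploid") {
    data.frame(group = "diploid", total_copies = sum(arrays$copies))
  } else {
    agg <- stats::aggregate(copies ~ haplotype, data = arrays, FUN = sum)
    names(agg) <- c("haplotype", "total_copies")
    agg
  }
}
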