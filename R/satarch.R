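# Satellite architecture: merge annotations into arrays, classify arrays by
# genomic context, partition HOR arrays into mini/normal centromeres, and
# compare haplotype array pairs.

#' Merge satellite annotations into arrays
#'
#' Same-family annotations on a chromosome are merged when their
#' inter-annotation gap is at most `max_gap_bp`; merged arrays shorter than
#' `min_array_bp` are discarded. `covered_bp` is the number of bases
#' actually covered by member annotations (overlaps counted once).
#'
#' @param annotations data.frame with `chrom`, `start`, `end`, `family`
#'   (0-based half-open), optionally `strand`.
#' @param max_gap_bp maximal merged gap (default 10000).
#' @param min_array_bp minimal array length kept (default 10000).
#' @return data.frame of arrays: `chrom`, `start`, `end`, `family`,
#'   `n_members`, `covered_bp`, sorted; non-overlapping within a family.
#' @export
merge_to_arrays <- function(annotations, max_gap_bp = 10000,
                            min_array_bp = 10000) {
  annotations <- check_intervals(annotations, what = "satellite annotations",
                                 required = c("chrom", "start", "end",
                                              "family"))
  if (any(!nzchar(annotations$family))) {
    stop("satellite annotations: empty family label")
  }
  if (!nrow(annotations)) {
    return(empty_bed(family = character(), n_members = integer(),
                     covered_bp = numeric()))
  }
  out <- NULL
  for (key in unique(paste(annotations$chrom, annotations$family, sep = "\r"))) {
    part <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ann <- annotations[annotations$chrom == part[1] &
                         annotations$family == part[2], , drop = FALSE]
    ir <- IRanges::IRanges(start = ann$start + 1, end = ann$end)
    merged <- IRanges::reduce(ir, min.gapwidth = max_gap_bp + 1)
    ov <- IRanges::findOverlaps(ir, merged)
    for (j in seq_along(merged)) {
      members <- ir[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
      out <- rbind(out, data.frame(
        chrom = part[1],
        start = IRanges::start(merged)[j] - 1,
        end = IRanges::end(merged)[j],
        family = part[2],
        n_members = length(members),
        covered_bp = sum(IRanges::width(IRanges::reduce(members)))))
    }
  }
  out <- out[out$end - out$start >= min_array_bp, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_alphasat <- function(family) grepl("^alpha", family, ignore.case = TRUE)
is_rdna <- function(family) tolower(family) == "rdna"

#' Classify satellite arrays by genomic context
#'
#' Per array: `rdna` if the family is rDNA; `subterminal` (arm `p` or `q`)
#' if the array starts within `end_window_bp` of the chromosome start or
#' ends within `end_window_bp` of the chromosome end; `centromeric_hor` if
#' the family is an alpha-satellite HOR family and the array is the largest
#' such non-subterminal array on its chromosome; otherwise `interstitial`.
#'
#' Identifying the centromere with the largest non-subterminal
#' alpha-satellite array is a deliberate simplification of active-array
#' identification (which would use HOR/SF annotation and CDR support).
#'
#' @param arrays data.frame from [merge_to_arrays()].
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param end_window_bp window defining "subterminal" (default 500000).
#' @return `arrays` with `class` and `arm` columns added.
#' @export
classify_arrays <- function(arrays, chrom_lengths, end_window_bp = 500000) {
  arrays <- check_intervals(arrays, what = "arrays",
                            required = c("chrom", "start", "end", "family"))
  if (!nrow(arrays)) {
    arrays$class <- character(); arrays$arm <- character()
    return(arrays)
  }
  if (any(!arrays$chrom %in% names(chrom_lengths))) {
    stop("classify_arrays: missing chromosome length for some arrays")
  }
  L <- chrom_lengths[arrays$chrom]
  stopifnot(all(arrays$end <= L))
  near_p <- arrays$start < end_window_bp
  near_q <- arrays$end > L - end_window_bp
  cls <- rep("interstitial", nrow(arrays))
  arm <- rep("unknown", nrow(arrays))
  cls[near_p | near_q] <- "subterminal"
  arm[near_p] <- "p"
  arm[near_q & !near_p] <- "q"
  cls[is_rdna(arrays$family)] <- "rdna"
  arm[is_rdna(arrays$family)] <- "unknown"
  # largest non-subterminal alpha-satellite array per chromosome
  cand <- which(is_alphasat(arrays$family) & cls == "interstitial")
  if (length(cand)) {
    for (ch in unique(arrays$chrom[cand])) {
      k <- cand[arrays$chrom[cand] == ch]
      cls[k[which.max(arrays$end[k] - arrays$start[k])]] <- "centromeric_hor"
    }
  }
  arrays$class <- cls
  arrays$arm <- arm
  arrays
}

#' Partition HOR array lengths into minicentromeres and normal centromeres
#'
#' Minicentromeres are alpha-satellite HOR arrays shorter than 700 kb.
#'
#' @param array_lengths positive lengths (bp).
#' @param threshold_bp partition threshold (default 700000).
#' @return list with `mini` (lengths < threshold, input order preserved)
#'   and `normal` (the rest).
#' @export
minicentromere_partition <- function(array_lengths, threshold_bp = 700000) {
  stopifnot(all(array_lengths > 0))
  list(mini = array_lengths[array_lengths < threshold_bp],
       normal = array_lengths[array_lengths >= threshold_bp])
}

#' Haplotype array-pair size and divergence statistics
#'
#' For each homologous array pair, the fold ratio is max/min of the two
#' haplotype lengths. Reported are the percentage of pairs exceeding
#' `fold_threshold` and the percentage exceeding `div_threshold` sequence
#' divergence (pairs with missing divergence are excluded from the
#' divergence denominator). Percentages are rounded half-up at 1 dp.
#'
#' @param pairs data.frame with `len_h1`, `len_h2` (bp, positive) and
#'   optionally `divergence` (fraction in \[0,1\] or NA).
#' @param fold_threshold fold-change threshold (default 1.5).
#' @param div_threshold divergence threshold (default 0.05).
#' @return list: `fraction_fold_exceeding`, `fraction_div_exceeding`
#'   (percentages), `n_pairs`, `n_div_pairs`, `fold_ratios`.
#' @export
haplotype_pair_stats <- function(pairs, fold_threshold = 1.5,
                                 div_threshold = 0.05) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(c("len_h1", "len_h2") %in% names(pairs)))
  if (any(pairs$len_h1 <= 0 | pairs$len_h2 <= 0)) {
    stop("haplotype_pair_stats: zero or negative array length")
  }
  fold <- pmax(pairs$len_h1, pairs$len_h2) / pmin(pairs$len_h1, pairs$len_h2)
  res <- list(
    fraction_fold_exceeding = fraction_pct(sum(fold > fold_threshold),
                                           length(fold)),
    fraction_div_exceeding = NA_real_,
    n_pairs = length(fold), n_div_pairs = 0L, fold_ratios = fold)
  if ("divergence" %in% names(pairs)) {
    d <- pairs$divergence[!is.na(pairs$divergence)]
    stopifnot(all(d >= 0 & d <= 1))
    if (length(d)) {
      res$fraction_div_exceeding <- fraction_pct(sum(d > div_threshold),
                                                 length(d))
      res$n_div_pairs <- length(d)
    }
  }
  res
}
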