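# Subterminal heterochromatin: cap detection, tract/spacer decomposition,
# periodicity statistics, and spacer-centred methylation profiles with a
# hypomethylation-pocket test.

#' Detect subterminal heterochromatic caps
#'
#' Per chromosome arm, a cap is the span of a chain of same-family
#' satellite arrays anchored at a subterminal-class array: all arrays of
#' the anchoring family on the chromosome are clustered by gaps of at most
#' `max_merge_gap_bp` (spacer scale), and every cluster containing a
#' subterminal array becomes a cap, provided its total satellite content
#' reaches `min_cap_bp`. The chaining matters because only the outermost
#' tract of a multi-megabase cap lies within the subterminal window; the
#' inner tracts are recruited through the spacer-scale gaps.
#'
#' @param arrays classified arrays from [classify_arrays()] (columns
#'   `chrom`, `start`, `end`, `family`, `class`, `arm`).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param max_merge_gap_bp maximal chained gap between cap arrays
#'   (default 200000, the upper spacer scale).
#' @param min_cap_bp minimal total satellite bp per cap (default 100000).
#' @return data.frame of caps: `chrom`, `start`, `end`, `arm`,
#'   `satellite_bp`.
#' @export
detect_caps <- function(arrays, chrom_lengths, max_merge_gap_bp = 200000,
                        min_cap_bp = 100000) {
  sub <- arrays[arrays$class == "subterminal", , drop = FALSE]
  out <- empty_bed(arm = character(), satellite_bp = numeric())
  if (!nrow(sub)) return(out)
  for (ch in unique(sub$chrom)) {
    fams <- unique(sub$family[sub$chrom == ch])
    a <- arrays[arrays$chrom == ch & arrays$family %in% fams &
                  arrays$class %in% c("subterminal", "interstitial"), ,
                drop = FALSE]
    ir <- IRanges::IRanges(a$start + 1, a$end)
    clusters <- IRanges::reduce(ir, min.gapwidth = max_merge_gap_bp + 1)
    ov <- IRanges::findOverlaps(ir, clusters)
    cl_of <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (j in seq_along(clusters)) {
      members <- a[cl_of == j, , drop = FALSE]
      anchors <- members[members$class == "subterminal", , drop = FALSE]
      if (!nrow(anchors)) next
      sat <- sum(members$end - members$start)
      if (sat < min_cap_bp) next
      out <- rbind(out, data.frame(
        chrom = ch, start = IRanges::start(clusters)[j] - 1,
        end = IRanges::end(clusters)[j], arm = anchors$arm[1],
        satellite_bp = sat))
    }
  }
  rownames(out) <- NULL
  out
}

#' Find spacers between satellite tracts inside a cap
#'
#' Spacers are the unannotated gaps between consecutive satellite tracts
#' within the cap, kept when their length lies in
#' \[`min_spacer_bp`, `max_spacer_bp`\]. The modal length is the most
#' frequent `bin_bp` bin of spacer lengths (bin floor; ties broken toward
#' the smaller bin), reported in bp.
#'
#' @param cap one-row data.frame or list with `chrom`, `start`, `end`.
#' @param annotations satellite annotation data.frame (`chrom`, `start`,
#'   `end`, `family`); tracts are annotations overlapping the cap.
#' @param min_spacer_bp,max_spacer_bp spacer length filter (defaults
#'   5000/200000).
#' @param bin_bp modal-length bin size (default 1000).
#' @return list: `spacers` (data.frame `chrom`, `start`, `end`, `midpoint`,
#'   `left_tract`, `right_tract`), `modal_length_bp` (NA when no spacers),
#'   `tracts` (the tract intervals used).
#' @export
find_spacers <- function(cap, annotations, min_spacer_bp = 5000,
                         max_spacer_bp = 200000, bin_bp = 1000) {
  ann <- annotations[annotations$chrom == cap$chrom &
                       annotations$end > cap$start &
                       annotations$start < cap$end, , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  empty <- list(spacers = empty_bed(midpoint = numeric(),
                                    left_tract = integer(),
                                    right_tract = integer()),
                modal_length_bp = NA_real_, tracts = ann)
  if (nrow(ann) < 2) return(empty)
  # collapse touching/overlapping annotations into tracts first
  ir <- IRanges::reduce(IRanges::IRanges(ann$start + 1, ann$end))
  tracts <- data.frame(chrom = cap$chrom, start = IRanges::start(ir) - 1,
                       end = IRanges::end(ir))
  empty$tracts <- tracts
  if (nrow(tracts) < 2) return(empty)
  gs <- tracts$end[-nrow(tracts)]
  ge <- tracts$start[-1]
  keep <- which(ge - gs >= min_spacer_bp & ge - gs <= max_spacer_bp)
  if (!length(keep)) return(empty)
  spacers <- data.frame(chrom = cap$chrom, start = gs[keep], end = ge[keep],
                        midpoint = floor((gs[keep] + ge[keep]) / 2),
                        left_tract = keep, right_tract = keep + 1L)
  lens <- spacers$end - spacers$start
  bins <- floor(lens / bin_bp)
  tab <- table(bins)
  top <- as.integer(names(tab)[tab == max(tab)])
  list(spacers = spacers, modal_length_bp = min(top) * bin_bp,
       tracts = tracts)
}

#' Tract and spacer periodicity statistics for a cap
#'
#' @param tracts tract interval data.frame (from [find_spacers()]).
#' @param spacers spacer data.frame (from [find_spacers()]).
#' @return list: `tract_mean_bp`, `tract_sd_bp` (NA for a single tract),
#'   `n_tracts`, `mean_spacing_bp` (mean distance between consecutive
#'   spacer midpoints; NA with fewer than two spacers), `n_spacers`.
#' @export
tract_stats <- function(tracts, spacers) {
  stopifnot(nrow(tracts) >= 1)
  tl <- tracts$end - tracts$start
  spacing <- if (nrow(spacers) >= 2) mean(diff(sort(spacers$midpoint)))
    else NA_real_
  list(tract_mean_bp = mean(tl),
       tract_sd_bp = if (length(tl) > 1) stats::sd(tl) else NA_real_,
       n_tracts = nrow(tracts),
       mean_spacing_bp = spacing, n_spacers = nrow(spacers))
}

#' Spacer-centred methylation profile and hypomethylation-pocket test
#'
#' Per-CpG fractions within `flank_bp` of each spacer midpoint are binned
#' by offset from the midpoint (`bin_bp` bins) and averaged across
#' spacers. The pocket statistic is (mean fraction inside the spacers)
#' minus (mean fraction in the flanking satellite within `flank_bp` of the
#' midpoints, excluding CpGs inside any spacer), with a one-sided
#' Wilcoxon rank-sum test (spacer < flank) on the per-CpG values.
#'
#' @param spacers spacer data.frame (`chrom`, `start`, `end`, `midpoint`).
#' @param track methylation track data.frame.
#' @param flank_bp half-width of the profile window (default 25000).
#' @param bin_bp profile bin width (default 500).
#' @return list: `profile` (data.frame `offset` = bin start relative to the
#'   midpoint, `mean_fraction`, `sd_fraction` (NA where a bin has a single
#'   value), `n`), `pocket_statistic`, `p_value`, `n_inside`, `n_flank`.
#' @export
spacer_methylation_profile <- function(spacers, track, flank_bp = 25000,
                                       bin_bp = 500) {
  stopifnot(nrow(spacers) >= 1)
  inside <- numeric(0); flank <- numeric(0)
  offs <- numeric(0); vals <- numeric(0)
  for (i in seq_len(nrow(spacers))) {
    mid <- spacers$midpoint[i]
    tr <- track_subset(track, spacers$chrom[i], mid - flank_bp, mid + flank_bp)
    if (!nrow(tr)) next
    off <- tr$start - mid
    offs <- c(offs, off); vals <- c(vals, tr$fraction)
    in_this <- tr$start >= spacers$start[i] & tr$start < spacers$end[i]
    in_other <- rep(FALSE, nrow(tr))
    others <- spacers[-i, , drop = FALSE]
    others <- others[others$chrom == spacers$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(others))) {
      in_other <- in_other | (tr$start >= others$start[j] &
                                tr$start < others$end[j])
    }
    inside <- c(inside, tr$fraction[in_this])
    flank <- c(flank, tr$fraction[!in_this & !in_other])
  }
  if (!length(vals)) stop("no CpGs in any spacer window")
  bin <- floor(offs / bin_bp) * bin_bp
  prof <- do.call(rbind, lapply(split(vals, bin), function(v) {
    data.frame(mean_fraction = mean(v),
               sd_fraction = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  prof <- data.frame(offset = as.numeric(rownames(prof)), prof)
  prof <- prof[order(prof$offset), , drop = FALSE]
  rownames(prof) <- NULL
  stat <- mean(inside) - mean(flank)
  p <- if (length(inside) && length(flank)) {
    suppressWarnings(stats::wilcox.test(inside, flank,
                                        alternative = "less")$p.value)
  } else NA_real_
  list(profile = prof, pocket_statistic = stat, p_value = p,
       n_inside = length(inside), n_flank = length(flank))
}

#' Exact cap bookkeeping: tracts + spacers + margins = cap length
#'
#' @param cap one-row cap (`start`, `end`).
#' @param tracts,spacers interval data.frames within the cap.
#' @return list with `tract_bp`, `spacer_bp`, `margin_bp`, `cap_bp`.
#' @export
cap_partition <- function(cap, tracts, spacers) {
  cap_bp <- cap$end - cap$start
  tract_bp <- sum(pmin(tracts$end, cap$end) - pmax(tracts$start, cap$start))
  spacer_bp <- sum(spacers$end - spacers$start)
  list(tract_bp = tract_bp, spacer_bp = spacer_bp,
       margin_bp = cap_bp - tract_bp - spacer_bp, cap_bp = cap_bp)
}
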