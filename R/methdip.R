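# CpG methylation smoothing and centromere dip region (CDR) calling. A CDR
# is a stretch of hypomethylated CpGs within a centromeric satellite array,
# called here by a median-relative drop rule over sliding windows.

track_subset <- function(track, chrom, start, end) {
  track[track$chrom == chrom & track$start >= start & track$start < end, ,
        drop = FALSE]
}

#' Windowed mean methylation over a region
#'
#' Windows of `window_bp` advance by `step_bp` from the region start and
#' are clipped at the region end; each CpG contributes equally (unweighted
#' by coverage). Windows without CpGs carry `NA` means.
#'
#' @param track methylation track data.frame (`chrom`, `start`, `end`,
#'   `coverage`, `fraction`).
#' @param region one-row data.frame or list with `chrom`, `start`, `end`.
#' @param window_bp window width; `window_bp >= step_bp > 0`.
#' @param step_bp window step.
#' @return data.frame: `start`, `end`, `mean_fraction` (NA when empty),
#'   `n_cpg`.
#' @export
binned_methylation <- function(track, region, window_bp, step_bp = window_bp) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  tr <- track_subset(track, region$chrom, region$start, region$end)
  starts <- seq(region$start, max(region$start, region$end - 1), by = step_bp)
  ends <- pmin(starts + window_bp, region$end)
  nwin <- length(starts)
  sums <- numeric(nwin)
  ns <- integer(nwin)
  if (nrow(tr)) {
    # a CpG at p falls in windows k_hi, k_hi-1, ... while p < start_k + window
    k_hi <- floor((tr$start - region$start) / step_bp) + 1L
    for (j in 0:(ceiling(window_bp / step_bp) - 1L)) {
      k <- k_hi - j
      ok <- k >= 1L & (tr$start - (region$start + (k - 1) * step_bp)) < window_bp
      if (!any(ok)) next
      agg <- rowsum(cbind(tr$fraction[ok], 1), k[ok])
      ki <- as.integer(rownames(agg))
      sums[ki] <- sums[ki] + agg[, 1]
      ns[ki] <- ns[ki] + as.integer(agg[, 2])
    }
  }
  data.frame(start = starts, end = ends,
             mean_fraction = ifelse(ns > 0, sums / ifelse(ns > 0, ns, 1),
                                    NA_real_),
             n_cpg = ns)
}

#' Call centromere dip regions (CDRs) within an array
#'
#' The baseline is the median of defined window means across the array.
#' Dip windows have mean below `baseline - drop`; consecutive dip windows
#' (tolerating up to `merge_gap_windows` non-dip windows in between) merge
#' into one CDR spanning from the first to the last dip window. CDRs
#' shorter than `min_len_bp` are discarded; any CDR spans that still
#' overlap (possible because windows are wider than the step) are merged.
#' An entirely hypomethylated array yields no CDRs, because the baseline
#' itself drops: the rule is relative by design.
#'
#' @param track methylation track data.frame.
#' @param array one-row data.frame or list with `chrom`, `start`, `end`
#'   (and optionally `array_id`).
#' @param window_bp,step_bp window geometry (defaults 5000/1000).
#' @param drop required drop below baseline in methylation fraction
#'   (default 0.20).
#' @param min_len_bp minimal CDR length kept (default 1000).
#' @param merge_gap_windows non-dip windows tolerated inside a CDR
#'   (default 2).
#' @return data.frame of CDRs: `chrom`, `start`, `end`, `array_id`,
#'   `mean_inside`, `mean_flanking` (mean over array CpGs outside any CDR).
#' @export
call_cdrs <- function(track, array, window_bp = 5000, step_bp = 1000,
                      drop = 0.20, min_len_bp = 1000, merge_gap_windows = 2) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      array_id = character(), mean_inside = numeric(),
                      mean_flanking = numeric())
  id <- if (!is.null(array$array_id)) array$array_id else
    sprintf("%s:%d-%d", array$chrom, array$start, array$end)
  bins <- binned_methylation(track, array, window_bp, step_bp)
  defined <- !is.na(bins$mean_fraction)
  if (!any(defined)) {
    warning(sprintf("array %s has no CpGs; no CDRs called", id))
    return(empty)
  }
  baseline <- stats::median(bins$mean_fraction[defined])
  dip <- defined & bins$mean_fraction < baseline - drop
  if (!any(dip)) return(empty)
  # group dip windows, tolerating short non-dip interruptions
  di <- which(dip)
  grp <- cumsum(c(1, diff(di) > merge_gap_windows + 1))
  # windows overlapping a dip edge are flagged from ~half a window away, so
  # trim the boundary blur of (window - step)/2 from each side of the span
  trim <- floor((window_bp - step_bp) / 2)
  spans <- do.call(rbind, lapply(split(di, grp), function(k) {
    s <- bins$start[min(k)]
    e <- min(bins$end[max(k)], array$end)
    if (e - s >= 2 * trim + step_bp) {
      s <- s + trim
      e <- e - trim
    }
    data.frame(start = s, end = e)
  }))
  spans <- spans[spans$end - spans$start >= min_len_bp, , drop = FALSE]
  if (!nrow(spans)) return(empty)
  ir <- IRanges::reduce(IRanges::IRanges(spans$start + 1, spans$end))
  spans <- data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  tr <- track_subset(track, array$chrom, array$start, array$end)
  in_any <- rep(FALSE, nrow(tr))
  out <- NULL
  for (j in seq_len(nrow(spans))) {
    inside <- tr$start >= spans$start[j] & tr$start < spans$end[j]
    in_any <- in_any | inside
    out <- rbind(out, data.frame(
      chrom = array$chrom, start = spans$start[j], end = spans$end[j],
      array_id = id,
      mean_inside = mean(tr$fraction[inside]),
      mean_flanking = NA_real_))
  }
  out$mean_flanking <- mean(tr$fraction[!in_any])
  out
}

#' Regress total CDR length on array length
#'
#' Ordinary least squares of per-array total CDR length against array
#' length; R^2 = 1 - SS_res/SS_tot. "CDR length" is the summed length of
#' all CDRs of the array, which handles multi-dip arrays deterministically.
#'
#' @param pairs data.frame with `array_length_bp` and `cdr_length_bp`
#'   (>= 3 rows; array lengths must vary).
#' @return list: `slope`, `intercept`, `r_squared`, `slope_ci` (95%
#'   confidence interval), `n`.
#' @export
cdr_length_vs_array_regression <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 3,
            all(c("array_length_bp", "cdr_length_bp") %in% names(pairs)))
  if (stats::var(pairs$array_length_bp) == 0) {
    stop("degenerate regression: array lengths are all equal")
  }
  fit <- stats::lm(cdr_length_bp ~ array_length_bp, data = pairs)
  ci <- suppressWarnings(stats::confint(fit, "array_length_bp", level = 0.95))
  r2 <- if (stats::var(pairs$cdr_length_bp) == 0) 0
    else suppressWarnings(summary(fit)$r.squared)  # constant y: SS_res = SS_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, slope_ci = unname(ci[1, ]), n = nrow(pairs))
}
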