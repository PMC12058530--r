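# Inversion phylogenetics: Fitch small parsimony with a reference root
# state, branch assignment and recurrence flagging, recall against prior
# callsets, and permutation tests of breakpoint feature enrichment.

#' Minimum-change count and branch assignment for a presence/absence
#' character on a rooted tree
#'
#' Counts the minimum number of state changes (Sankoff/Fitch small
#' parsimony with unit costs) with the root fixed to "reference" --
#' inversions are treated as derived, which gives every change a
#' direction and makes single-change characters assignable to the branch
#' on which the gain occurred. Characters needing two or more changes are
#' flagged recurrent. Missing leaves are uninformative (either state at
#' zero cost).
#'
#' @param presence named logical vector over the tree's tip labels:
#'   `TRUE` = inversion present (homozygous), `FALSE` = reference, `NA` =
#'   missing/heterozygous. At least two non-missing values are required.
#' @param tree rooted binary [ape::phylo]; branches are named by their
#'   child node (tip labels / node labels, `nodeN` when unlabelled).
#' @return list: `changes` (minimum number of changes), `branch` (child
#'   node name of the gain branch when `changes == 1`, else NA),
#'   `recurrent` (`changes >= 2`), `candidates` (all branch names whose
#'   clade matches the presence pattern; ties resolved toward the
#'   smallest clade).
#' @export
fitch_assign <- function(presence, tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  stopifnot(all(names(presence) %in% tips))
  presence <- presence[tips[tips %in% names(presence)]]
  defined <- !is.na(presence)
  if (sum(defined) < 2) stop("character defined for fewer than two species")
  nt <- length(tips)
  nn <- nt + tree$Nnode
  # cost[node, s]: min changes in the subtree given node state s
  # (s = 1 reference/absent, s = 2 inverted/present)
  cost <- matrix(0, nn, 2)
  tip_state <- presence[match(tips, names(presence))]
  cost[which(tip_state), 1] <- Inf
  cost[which(!tip_state), 2] <- Inf
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    cost[par, 1] <- cost[par, 1] + min(cost[ch, 1], cost[ch, 2] + 1)
    cost[par, 2] <- cost[par, 2] + min(cost[ch, 2], cost[ch, 1] + 1)
  }
  root <- nt + 1L
  changes <- cost[root, 1]
  nms <- node_names(tree)
  candidates <- character(0)
  branch <- NA_character_
  if (is.finite(changes) && changes == 1) {
    present_tips <- names(presence)[defined & presence]
    absent_tips <- names(presence)[defined & !presence]
    clades <- lapply(tree$edge[, 2], clade_tips, tree = tree)
    ok <- vapply(clades, function(cl) {
      all(present_tips %in% cl) && !any(absent_tips %in% cl) &&
        length(present_tips) > 0
    }, logical(1))
    if (any(ok)) {
      sizes <- lengths(clades)[ok]
      cand_nodes <- tree$edge[ok, 2]
      ord <- order(sizes)
      candidates <- nms[cand_nodes][ord]
      branch <- candidates[1]
    }
  }
  list(changes = unname(changes), branch = branch,
       recurrent = is.finite(changes) && changes >= 2,
       candidates = candidates)
}

#' Collapse per-haplotype inversion genotypes to per-species presence
#'
#' A species is "present" when homozygous inverted; heterozygous species
#' are treated as missing unless `include_heterozygous = TRUE` (then they
#' count as present, for sensitivity analysis). Accepts either one
#' genotype column per species (values `inv`/`ref`/`missing`) or two
#' per-haplotype columns named `<species>_h1`/`<species>_h2`.
#'
#' @param genotypes named character vector of genotype values.
#' @param species species (tip) names expected.
#' @param include_heterozygous logical (default FALSE).
#' @return named logical vector over `species` (NA = missing).
#' @export
presence_from_genotypes <- function(genotypes, species,
                                    include_heterozygous = FALSE) {
  out <- stats::setNames(rep(NA, length(species)), species)
  for (sp in species) {
    h <- genotypes[paste0(sp, c("_h1", "_h2"))]
    if (all(!is.na(names(h)) & paste0(sp, c("_h1", "_h2")) %in%
              names(genotypes))) {
      g <- unname(genotypes[paste0(sp, c("_h1", "_h2"))])
      if (any(g == "missing")) next
      n_inv <- sum(g == "inv")
      out[sp] <- if (n_inv == 2) TRUE
        else if (n_inv == 0) FALSE
        else if (include_heterozygous) TRUE else NA
    } else if (sp %in% names(genotypes)) {
      g <- genotypes[[sp]]
      out[sp] <- switch(g, inv = TRUE, ref = FALSE, NA)
    }
  }
  out
}

#' Assign a table of inversion characters to tree branches
#'
#' @param genotypes data.frame with `event_id` plus genotype columns (see
#'   [presence_from_genotypes()]).
#' @param tree rooted [ape::phylo].
#' @param include_heterozygous passed through.
#' @return data.frame: `event_id`, `changes`, `branch`, `recurrent`.
#' @export
assign_inversions <- function(genotypes, tree, include_heterozygous = FALSE) {
  species <- tree$tip.label
  out <- lapply(seq_len(nrow(genotypes)), function(i) {
    row <- genotypes[i, , drop = FALSE]
    gvec <- unlist(lapply(row, as.character))
    pres <- presence_from_genotypes(gvec, species, include_heterozygous)
    fa <- fitch_assign(pres, tree)
    data.frame(event_id = row$event_id, changes = fa$changes,
               branch = fa$branch, recurrent = fa$recurrent)
  })
  do.call(rbind, out)
}

#' Regress per-branch inversion counts on branch lengths
#'
#' @param counts numeric vector of events assigned per branch.
#' @param lengths branch lengths (Ma), same order.
#' @return list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
branch_count_regression <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), length(counts) >= 3)
  if (stats::var(lengths) == 0) stop("degenerate regression: equal lengths")
  fit <- stats::lm(counts ~ lengths)
  r2 <- if (stats::var(counts) == 0) 0
    else suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(counts))
}

#' Fraction of previously reported calls confirmed by the current callset
#'
#' A previous call is confirmed when some current call on the same
#' chromosome reciprocally overlaps it by at least
#' `min_reciprocal_overlap` of each interval. The fraction is reported as
#' a percentage rounded half-up at 1 dp.
#'
#' @param current,previous interval data.frames (`chrom`, `start`, `end`).
#' @param min_reciprocal_overlap reciprocal overlap threshold (default 0.5).
#' @return list: `percent_confirmed`, `n_confirmed`, `n_previous`.
#' @export
recall_vs_previous <- function(current, previous,
                               min_reciprocal_overlap = 0.5) {
  previous <- check_intervals(previous, "previous calls")
  current <- check_intervals(current, "current calls")
  if (!nrow(previous)) stop("empty previous callset")
  confirmed <- rep(FALSE, nrow(previous))
  if (nrow(current)) {
    prev_gr <- as_granges0(previous)
    cur_gr <- as_granges0(current)
    ov <- GenomicRanges::findOverlaps(prev_gr, cur_gr)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      inter <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(prev_gr)[qh], IRanges::ranges(cur_gr)[sh]))
      ok <- inter >= min_reciprocal_overlap * IRanges::width(prev_gr)[qh] &
        inter >= min_reciprocal_overlap * IRanges::width(cur_gr)[sh]
      confirmed[unique(qh[ok])] <- TRUE
    }
  }
  list(percent_confirmed = fraction_pct(sum(confirmed), nrow(previous)),
       n_confirmed = sum(confirmed), n_previous = nrow(previous))
}

# Per-chromosome sorted lookup of merged (optionally padded) intervals.
interval_lookup <- function(intervals, pad_bp = 0) {
  if (is.null(intervals) || !nrow(intervals)) return(list())
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(pmax(intervals$start - pad_bp, 0) + 1,
                     intervals$end + pad_bp)))
  df <- as_bed0(gr)
  split(df[, c("start", "end")], df$chrom)
}

# Do 0-based point positions fall inside looked-up intervals?
points_in_lookup <- function(pos, chrom, lookup) {
  hit <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    lk <- lookup[[ch]]
    if (is.null(lk)) next
    k <- chrom == ch
    idx <- findInterval(pos[k], lk$start)
    hit[k] <- idx > 0 & pos[k] < lk$end[pmax(idx, 1)]
  }
  hit
}

#' Count inversions with a breakpoint inside a feature set
#'
#' A breakpoint "hits" when it falls inside a feature interval, features
#' being padded by `pad_bp` on each side (breakpoints from assembly
#' comparisons are not base-precise).
#'
#' @param inversions interval data.frame (`chrom`, `start`, `end`); the
#'   two breakpoints of each inversion are its interval ends.
#' @param features interval data.frame.
#' @param pad_bp feature padding (default 10000).
#' @return integer: number of inversions with >= 1 breakpoint in a feature.
#' @export
count_breakpoint_hits <- function(inversions, features, pad_bp = 10000) {
  lookup <- interval_lookup(features, pad_bp)
  hit1 <- points_in_lookup(inversions$start, inversions$chrom, lookup)
  hit2 <- points_in_lookup(inversions$end - 1, inversions$chrom, lookup)
  sum(hit1 | hit2)
}

#' Permutation test of feature enrichment at inversion breakpoints
#'
#' The observed statistic is the number of inversions with at least one
#' breakpoint inside a (padded) feature. The null redraws each inversion
#' uniformly on its own chromosome with its length preserved, excluding
#' placements that overlap assembly gaps; inter-chromosomal shuffling is
#' not performed, conserving per-chromosome feature density. Fold =
#' observed / mean(null); the one-sided empirical P uses the +1
#' correction, so P >= 1/(n_perm + 1).
#'
#' @param inversions interval data.frame (`chrom`, `start`, `end`).
#' @param features interval data.frame of features (e.g. segmental
#'   duplications).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param gaps optional interval data.frame of assembly gaps.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param pad_bp breakpoint/feature padding (default 10000).
#' @return list: `observed`, `null_mean`, `null_sd`, `fold`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
breakpoint_feature_enrichment <- function(inversions, features,
                                          chrom_lengths, gaps = NULL,
                                          n_perm = 1000, seed = 1,
                                          pad_bp = 10000) {
  stopifnot(n_perm >= 100)
  inversions <- check_intervals(inversions, "inversions")
  stopifnot(all(inversions$chrom %in% names(chrom_lengths)))
  if (is.null(features) || !nrow(features)) {
    warning("empty feature list: fold undefined, P = 1")
    return(list(observed = NA_integer_, null_mean = NA_real_,
                null_sd = NA_real_, fold = NA_real_, p_value = 1,
                n_perm = n_perm, seed = seed))
  }
  set.seed(as.integer(seed))
  lookup <- interval_lookup(features, pad_bp)
  gap_lookup <- interval_lookup(gaps, 0)
  observed <- count_breakpoint_hits(inversions, features, pad_bp)
  n <- nrow(inversions)
  len <- inversions$end - inversions$start
  L <- chrom_lengths[inversions$chrom]
  null <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    start <- floor(runif(n, 0, pmax(L - len, 1)))
    if (length(gap_lookup)) {
      # redraw placements overlapping a gap
      for (tries in 1:50) {
        bad <- placement_overlaps(start, len, inversions$chrom, gap_lookup)
        if (!any(bad)) break
        start[bad] <- floor(runif(sum(bad), 0, pmax(L[bad] - len[bad], 1)))
      }
    }
    hit1 <- points_in_lookup(start, inversions$chrom, lookup)
    hit2 <- points_in_lookup(start + len - 1, inversions$chrom, lookup)
    null[p] <- sum(hit1 | hit2)
  }
  list(observed = observed, null_mean = mean(null), null_sd = stats::sd(null),
       fold = observed / mean(null),
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

# Does interval [start, start+len) overlap any looked-up interval?
placement_overlaps <- function(start, len, chrom, lookup) {
  bad <- rep(FALSE, length(start))
  end <- start + len
  for (ch in unique(chrom)) {
    lk <- lookup[[ch]]
    if (is.null(lk)) next
    k <- which(chrom == ch)
    idx <- findInterval(end[k] - 1, lk$start)
    bad[k] <- idx > 0 & lk$end[pmax(idx, 1)] > start[k]
  }
  bad
}
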