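# Independent oracles, kept separate from the implementations they check.

# N50 by exhaustive candidate search: the largest length L in the list such
# that the lengths >= L sum to at least half the total (checked for every
# candidate, per the worked examples: {30,10,10} -> 30, {50,40,30,20,10} -> 40).
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# Minimum-change count for a presence/absence character on a rooted tree by
# brute force over all ancestral labellings, with the root fixed to absence.
fitch_oracle <- function(presence, tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  internal <- seq(nt + 1, nn)
  tip_state <- as.integer(presence[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^(length(internal)) - 1)) {
    lab <- integer(nn)
    lab[seq_len(nt)] <- tip_state
    lab[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1), 1)
    if (lab[nt + 1] != 0) next  # root constrained to reference
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Interval Jaccard on 0-based half-open intervals.
jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  inter / union
}

# Table 1 hap1 columns as printed (six assemblies).
table1_hap1 <- function() {
  data.frame(
    assembly = c("chimpanzee", "bonobo", "gorilla",
                 "bornean_orangutan", "sumatran_orangutan", "siamang"),
    total_bases_gb = c(3.14, 3.21, 3.55, 3.16, 3.17, 3.24),
    contig_n50_mb = c(146.29, 147.03, 151.43, 140.59, 146.20, 146.71),
    n_t2t = c(19, 20, 19, 15, 14, 24),
    n_issues = c(0, 0, 4, 1, 2, 0),
    qv = c(66.0, 62.7, 61.7, 65.8, 63.3, 66.4))
}

# Per-haplotype T2T contig counts (hap1, hap2) and chromosome counts per
# haplotype for the six assemblies (2n=48 species have 24 per haplotype;
# siamang 2n=50 has 25).
t2t_fixture_counts <- function() {
  data.frame(
    assembly = rep(c("chimpanzee", "bonobo", "gorilla", "bornean_orangutan",
                     "sumatran_orangutan", "siamang"), each = 2),
    haplotype = rep(c("h1", "h2"), 6),
    n_chromosomes = rep(c(24, 24, 24, 24, 24, 25), each = 2),
    n_t2t = c(19, 17, 20, 19, 19, 22, 15, 13, 14, 13, 24, 20))
}
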