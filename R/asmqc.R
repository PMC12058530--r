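# Assembly QC: telomere detection, gap accounting with rDNA exemption,
# contig N50, T2T classification and Table-style summaries. A chromosome is
# T2T when it is gapless with a telomere on both ends.

#' Detect terminal telomere runs
#'
#' Finds maximal tandem runs of the motif (or its reverse complement) of
#' length >= `min_run_bp` whose nearer end lies within `max_offset_bp` of a
#' sequence terminus. At most one interval is reported per terminus; a
#' single run may satisfy both terminus conditions (e.g. a sequence that is
#' entirely motif copies) and is then reported once per terminus.
#'
#' @param sequence DNA as a character string or [Biostrings::DNAString].
#' @param motif 6-mer telomere motif (default `"TTAGGG"`).
#' @param min_run_bp minimal run length (default 2000).
#' @param max_offset_bp maximal distance of the run's nearer end from a
#'   terminus (default 10000).
#' @return data.frame `chrom`-less interval table: `start`, `end`
#'   (0-based half-open), `terminus` (`"p"` or `"q"`).
#' @export
detect_telomeres <- function(sequence, motif = "TTAGGG",
                             min_run_bp = 2000, max_offset_bp = 10000) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "XString")) {
    sequence <- as.character(sequence)
  }
  stopifnot(is.character(sequence), nchar(sequence) > 0, nchar(motif) == 6)
  L <- nchar(sequence)
  runs <- rbind(motif_runs(sequence, motif),
                motif_runs(sequence, revcomp(motif)))
  runs <- runs[runs$end - runs$start >= min_run_bp, , drop = FALSE]
  out <- NULL
  if (nrow(runs)) {
    for (term in c("p", "q")) {
      d <- if (term == "p") runs$start else L - runs$end
      ok <- which(d <= max_offset_bp)
      if (length(ok)) {
        # nearest run to the terminus; tie broken toward the longer run
        best <- ok[order(d[ok], -(runs$end[ok] - runs$start[ok]))][1]
        out <- rbind(out, data.frame(start = runs$start[best],
                                     end = runs$end[best], terminus = term))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = numeric(), end = numeric(),
                      terminus = character())
  }
  out
}

# Maximal tandem runs of `motif` in `s`, as 0-based half-open intervals.
motif_runs <- function(s, motif) {
  m <- gregexpr(paste0("(?:", motif, ")+"), s)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  start <- as.numeric(m) - 1
  data.frame(start = start, end = start + attr(m, "match.length"))
}

#' Find assembly gaps (N runs) in a sequence
#'
#' A gap is a maximal run of at least `min_n` consecutive N.
#'
#' @param sequence character string or [Biostrings::DNAString].
#' @param min_n minimal N-run length counted as a gap (default 10).
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
find_gaps <- function(sequence, min_n = 10) {
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  m <- gregexpr(sprintf("N{%d,}", min_n), sequence)[[1]]
  if (m[1] == -1) return(data.frame(start = numeric(), end = numeric()))
  start <- as.numeric(m) - 1
  data.frame(start = start, end = start + attr(m, "match.length"))
}

#' Build a per-chromosome QC record
#'
#' @param name chromosome name.
#' @param length chromosome length (bp).
#' @param gaps interval data.frame (`start`, `end`) of N-run gaps.
#' @param telomeres data.frame as from [detect_telomeres()] (`start`,
#'   `end`, `terminus`).
#' @param rdna optional interval data.frame of rDNA arrays (for the gap
#'   exemption in [count_issues()]).
#' @param haplotype,species optional labels.
#' @return an object of class `chromosome_record`.
#' @export
chromosome_record <- function(name, length, gaps = NULL, telomeres = NULL,
                              rdna = NULL, haplotype = NA, species = NA) {
  empty <- data.frame(start = numeric(), end = numeric())
  if (is.null(gaps)) gaps <- empty
  if (is.null(rdna)) rdna <- empty
  if (is.null(telomeres)) {
    telomeres <- data.frame(start = numeric(), end = numeric(),
                            terminus = character())
  }
  stopifnot(length > 0, all(gaps$end <= length), all(gaps$start >= 0))
  gaps <- gaps[order(gaps$start), , drop = FALSE]
  out <- list(name = name, length = length, gaps = gaps,
              telomeres = telomeres, rdna = rdna,
              haplotype = haplotype, species = species)
  class(out) <- "chromosome_record"
  out
}

#' Build a chromosome record directly from sequence
#'
#' Convenience wrapper running [find_gaps()] and [detect_telomeres()].
#'
#' @param name chromosome name.
#' @param sequence character string or [Biostrings::DNAString].
#' @param rdna optional rDNA interval data.frame.
#' @param ... passed to [detect_telomeres()].
#' @return a `chromosome_record`.
#' @export
chromosome_record_from_sequence <- function(name, sequence, rdna = NULL, ...) {
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  chromosome_record(name, nchar(sequence), gaps = find_gaps(sequence),
                    telomeres = detect_telomeres(sequence, ...), rdna = rdna)
}

#' Classify a chromosome as T2T, gapped, or missing a telomere
#'
#' `t2t` iff there are zero gaps and a telomere at both termini; `gapped`
#' if there is at least one gap (taking precedence when a telomere is also
#' missing); `missing_telomere` if gapless but a terminus lacks a telomere.
#'
#' @param chrom a [chromosome_record()].
#' @return one of `"t2t"`, `"gapped"`, `"missing_telomere"`.
#' @export
classify_chromosome <- function(chrom) {
  stopifnot(inherits(chrom, "chromosome_record"))
  has_p <- "p" %in% chrom$telomeres$terminus
  has_q <- "q" %in% chrom$telomeres$terminus
  if (nrow(chrom$gaps) > 0) return("gapped")
  if (has_p && has_q) "t2t" else "missing_telomere"
}

#' Count gaps and non-rDNA issues for a chromosome
#'
#' A gap is exempt when it overlaps an rDNA interval; each missing terminus
#' telomere adds one non-rDNA issue.
#'
#' @param chrom a [chromosome_record()].
#' @return named numeric vector `c(n_gaps_total, n_non_rdna_issues)`.
#' @export
count_issues <- function(chrom) {
  stopifnot(inherits(chrom, "chromosome_record"))
  g <- chrom$gaps
  n_gaps <- nrow(g)
  non_rdna <- 0L
  if (n_gaps) {
    in_rdna <- vapply(seq_len(n_gaps), function(i) {
      any(g$start[i] < chrom$rdna$end & g$end[i] > chrom$rdna$start)
    }, logical(1))
    non_rdna <- sum(!in_rdna)
  }
  missing_tel <- 2L - sum(c("p", "q") %in% chrom$telomeres$terminus)
  c(n_gaps_total = n_gaps, n_non_rdna_issues = non_rdna + missing_tel)
}

#' Contig N50
#'
#' The smallest contig length L such that contigs of length >= L together
#' contain at least half of the total assembly.
#'
#' @param contig_lengths positive contig lengths (bp).
#' @return N50 in bp.
#' @examples
#' contig_n50(c(50, 40, 30, 20, 10)) # 40
#' @export
contig_n50 <- function(contig_lengths) {
  if (!length(contig_lengths)) stop("contig_n50: empty length list")
  stopifnot(all(contig_lengths > 0))
  s <- sort(contig_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Split a chromosome into contigs at its gaps
#'
#' @param length chromosome length (bp).
#' @param gaps gap interval data.frame (`start`, `end`).
#' @return numeric vector of contig lengths (zero-length pieces dropped).
#' @export
contigs_from_gaps <- function(length, gaps = NULL) {
  if (is.null(gaps) || !nrow(gaps)) return(length)
  g <- gaps[order(gaps$start), , drop = FALSE]
  # contigs are [0,g1s), [g1e,g2s), ..., [gke, length)
  starts <- c(0, g$end)
  ends <- c(g$start, length)
  lens <- ends - starts
  lens[lens > 0]
}

#' Summarize per-assembly QC statistics into an averages row
#'
#' Arithmetic means per column, rounded half-up at the printed precision:
#' 2 decimal places for the base-pair scale columns (`total_bases_gb`,
#' `contig_n50_mb`) and 1 decimal place for counts and QV.
#'
#' @param stats data.frame with one row per assembly; recognised columns
#'   are `total_bases_gb`, `contig_n50_mb`, `n_t2t`, `n_issues`, `qv`
#'   (missing ones are skipped; an all-NA column yields NA).
#' @return one-row data.frame of rounded column means.
#' @export
summarize_assemblies <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1)
  digits <- c(total_bases_gb = 2, contig_n50_mb = 2,
              n_t2t = 1, n_issues = 1, qv = 1)
  cols <- intersect(names(digits), names(stats))
  out <- lapply(cols, function(cn) {
    v <- stats[[cn]]
    if (all(is.na(v))) NA_real_
    else round_half_up(mean(v, na.rm = TRUE), digits[[cn]])
  })
  stats::setNames(as.data.frame(out), cols)
}

#' QC a whole assembly (set of chromosome records)
#'
#' @param records list of [chromosome_record()]s.
#' @param qv optional pass-through consensus accuracy value.
#' @return list with `per_chromosome` (name, length, status, n_gaps,
#'   n_non_rdna_issues), and `summary` (total_bases_gb, contig_n50_mb,
#'   n_t2t, n_issues, qv).
#' @export
qc_assembly <- function(records, qv = NA_real_) {
  stopifnot(length(records) >= 1)
  per <- do.call(rbind, lapply(records, function(r) {
    iss <- count_issues(r)
    data.frame(name = r$name, length = r$length,
               status = classify_chromosome(r),
               n_gaps = unname(iss[1]), n_non_rdna_issues = unname(iss[2]))
  }))
  contigs <- unlist(lapply(records, function(r) {
    contigs_from_gaps(r$length, r$gaps)
  }))
  list(per_chromosome = per,
       summary = data.frame(
         total_bases_gb = sum(per$length) / 1e9,
         contig_n50_mb = contig_n50(contigs) / 1e6,
         n_t2t = sum(per$status == "t2t"),
         n_issues = sum(per$n_non_rdna_issues),
         qv = qv))
}
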