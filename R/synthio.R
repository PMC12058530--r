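# Synthetic diploid assemblies with known truth: telomere runs, centromeric
# HOR arrays (optionally bimodal), subterminal satellite caps with periodic
# hypomethylated spacers, rDNA arrays, assembly gaps, CDR-bearing methylation
# tracks, and inversions evolved on a species tree.

# 32 bp AT-rich subterminal satellite monomer used by default for cap tracts.
# Two CpG sites per monomer so that methylation profiles over caps are
# measurable on synthetic sequence.
PCHT_MONOMER <- "CGAATATTTAAATTTCATTTGAACGTTAATTT"

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate a bonobo-like chromosome: a bimodal alpha-satellite HOR
#' array length distribution (minicentromere component with mean 110 kb,
#' normal component with mean 3.6 Mb, minicentromere weight 27/48), 32 bp
#' AT-rich subterminal satellite caps with ~400 kb tracts interrupted by
#' 32 kb spacers, 45 kb rDNA units, 5 kb telomeric TTAGGG runs, a CDR whose
#' length scales as 0.3 x array length, hypermethylated background (mean
#' 0.9) against hypomethylated CDRs and spacer pockets (mean 0.1).
#'
#' @param n_chromosomes chromosomes per haplotype.
#' @param chrom_length_bp chromosome length, a single value or a
#'   `c(min, max)` range sampled uniformly per chromosome.
#' @param telomere list: `motif` (6-mer, default TTAGGG), `run_bp` (target
#'   run length; rounded down to whole motif copies).
#' @param centromere list: `monomer_bp`, `monomers_per_unit`,
#'   `distribution` ("unimodal" or "bimodal"), `mixture_weight`
#'   (probability of the first, short component), `mean_bp` and `sd_factor`
#'   (lognormal components: arithmetic means and sdlog values), `range_bp`
#'   (2x2 matrix-like list of clamping ranges per component), and
#'   `substitution_rate` (per-base substitution applied to the tandem
#'   array; default 0 for a clean identity baseline).
#' @param cap list: `p_arm`/`q_arm` flags, `monomer` (32 bp AT-rich
#'   default), `n_tracts`, `tract_mean_bp`, `tract_sd_bp`, `spacer_bp`,
#'   and optional `period_bp` (sets `tract_mean_bp = period_bp - spacer_bp`).
#' @param rdna list: `unit_bp` (default 45000) and `copies` (integer vector
#'   recycled over chromosomes; 0 disables the array on that chromosome).
#' @param gaps list: `n` N-runs per chromosome and `length_bp` each.
#' @param methylation list: `background_mean`, `background_sd`, `cdr_mean`,
#'   `pocket_mean`, `coverage` (Poisson mean), `cdr_slope` and
#'   `cdr_noise_sd_bp` (truth CDR length = slope x array length + noise).
#' @param inversion list: `rate_per_ma` (events per Ma of branch length),
#'   `recurrent_fraction`, `size_range_bp`.
#' @param seed default seed used when an operation is not given one.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length_bp = 12e6,
                       telomere = list(),
                       centromere = list(),
                       cap = list(),
                       rdna = list(),
                       gaps = list(),
                       methylation = list(),
                       inversion = list(),
                       seed = 1L) {
  defaults <- list(
    telomere = list(motif = "TTAGGG", run_bp = 5000),
    centromere = list(monomer_bp = 171, monomers_per_unit = 6,
                      distribution = "bimodal",
                      mixture_weight = 27 / 48,
                      mean_bp = c(110e3, 3.6e6),
                      sdlog = c(0.7, 0.25),
                      range_bp = list(c(15e3, 674e3), c(1.6e6, 6.7e6)),
                      substitution_rate = 0),
    cap = list(p_arm = TRUE, q_arm = FALSE, monomer = PCHT_MONOMER,
               n_tracts = 8, tract_mean_bp = 4e5, tract_sd_bp = 5e4,
               spacer_bp = 32e3, period_bp = NULL),
    rdna = list(unit_bp = 45e3, copies = c(10L, 0L)),
    gaps = list(n = 0L, length_bp = 10e3),
    methylation = list(background_mean = 0.9, background_sd = 0.05,
                       cdr_mean = 0.1, pocket_mean = 0.1, coverage = 30,
                       cdr_slope = 0.3, cdr_noise_sd_bp = 10e3),
    inversion = list(rate_per_ma = 2, recurrent_fraction = 0,
                     size_range_bp = c(10e3, 100e3))
  )
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    telomere = utils::modifyList(defaults$telomere, telomere),
    centromere = utils::modifyList(defaults$centromere, centromere),
    cap = utils::modifyList(defaults$cap, cap, keep.null = TRUE),
    rdna = utils::modifyList(defaults$rdna, rdna),
    gaps = utils::modifyList(defaults$gaps, gaps),
    methylation = utils::modifyList(defaults$methylation, methylation),
    inversion = utils::modifyList(defaults$inversion, inversion),
    seed = as.integer(seed)
  )
  if (!is.null(cfg$cap$period_bp)) {
    cfg$cap$tract_mean_bp <- cfg$cap$period_bp - cfg$cap$spacer_bp
  }
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 0,
            all(cfg$chrom_length_bp > 0),
            length(cfg$chrom_length_bp) %in% c(1, 2),
            nchar(cfg$telomere$motif) == 6,
            cfg$telomere$run_bp > 0,
            cfg$centromere$mixture_weight >= 0,
            cfg$centromere$mixture_weight <= 1,
            all(cfg$centromere$mean_bp > 0),
            cfg$cap$spacer_bp > 0, cfg$cap$tract_mean_bp > 0,
            cfg$rdna$unit_bp > 0, all(cfg$rdna$copies >= 0),
            cfg$gaps$n >= 0, cfg$gaps$length_bp > 0,
            cfg$methylation$background_mean >= 0,
            cfg$methylation$background_mean <= 1,
            cfg$methylation$cdr_mean >= 0, cfg$methylation$cdr_mean <= 1,
            cfg$methylation$pocket_mean >= 0,
            cfg$methylation$pocket_mean <= 1,
            cfg$inversion$rate_per_ma >= 0,
            cfg$inversion$recurrent_fraction >= 0,
            cfg$inversion$recurrent_fraction <= 1)
  invisible(cfg)
}

TRUTH_TABLES <- c("chromosomes", "telomeres", "gaps", "satellites",
                  "arrays", "spacers", "cdrs", "rdna")

# Uniform i.i.d. background sequence; avoids accidental satellite structure.
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

mutate_dna <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  n <- nchar(s)
  k <- which(runif(n) < rate)
  if (!length(k)) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[k] <- c("A", "C", "G", "T")[sample.int(4L, length(k), replace = TRUE)]
  paste(v, collapse = "")
}

#' Sample alpha-satellite HOR array lengths from the configured distribution
#'
#' Draws from the unimodal or two-component lognormal mixture of the
#' centromere configuration; component draws are clamped to the configured
#' per-component ranges. Lognormal `meanlog` is set so the arithmetic mean
#' of each component equals `mean_bp`.
#'
#' @param config a [sim_config()].
#' @param n number of arrays.
#' @param seed integer seed.
#' @return data.frame with `length_bp` and `component` (1 = first/short
#'   component, 2 = second; always 1 for unimodal).
#' @export
sample_hor_lengths <- function(config, n, seed = config$seed) {
  set.seed(derive_seed(seed, 11L))
  cen <- config$centromere
  if (n == 0) return(data.frame(length_bp = numeric(), component = integer()))
  if (identical(cen$distribution, "unimodal")) {
    comp <- rep(1L, n)
  } else {
    comp <- ifelse(runif(n) < cen$mixture_weight, 1L, 2L)
  }
  mu <- log(cen$mean_bp) - cen$sdlog^2 / 2
  len <- rlnorm(n, meanlog = mu[comp], sdlog = cen$sdlog[comp])
  for (k in seq_along(cen$mean_bp)) {
    rng <- cen$range_bp[[k]]
    len[comp == k] <- pmin(pmax(len[comp == k], rng[1]), rng[2])
  }
  data.frame(length_bp = round(len), component = comp)
}

#' Sample truth CDR lengths given array lengths
#'
#' Truth CDR length = `cdr_slope` x array length + Gaussian noise
#' (`cdr_noise_sd_bp`), clamped to \[1 kb, 0.9 x array length\].
#'
#' @param array_lengths_bp numeric vector of array lengths.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return numeric vector of CDR lengths (bp).
#' @export
sample_cdr_lengths <- function(array_lengths_bp, config, seed = config$seed) {
  set.seed(derive_seed(seed, 12L))
  m <- config$methylation
  len <- m$cdr_slope * array_lengths_bp +
    rnorm(length(array_lengths_bp), 0, m$cdr_noise_sd_bp)
  pmin(pmax(round(len), 1000), floor(0.9 * array_lengths_bp))
}

#' Generate a synthetic diploid assembly with full ground truth
#'
#' Builds `n_chromosomes` chromosomes per haplotype, each laid out as
#' p-telomere, optional p-arm cap (satellite tracts alternating with
#' spacers), centromeric HOR array, optional rDNA array, optional q-arm
#' cap, q-telomere, with uniform-random background between features and
#' optional N-run gaps. Every placed feature is recorded in the truth
#' tables (BED-convention 0-based half-open intervals).
#'
#' @param config a [sim_config()].
#' @param seed integer; fixes all randomness (byte-identical outputs for
#'   identical `(config, seed)`).
#' @return an object of class `sim_assembly`: list with `sequences`
#'   (named [Biostrings::DNAStringSet]), `truth` (list of data.frames:
#'   `chromosomes`, `telomeres`, `gaps`, `satellites`, `arrays`, `spacers`,
#'   `cdrs`, `rdna`), `config`, `seed`.
#' @export
generate_assembly <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, 1L))
  haps <- c("h1", "h2")
  n <- config$n_chromosomes

  truth <- list(chromosomes = NULL, telomeres = NULL, gaps = NULL,
                satellites = NULL, arrays = NULL, spacers = NULL,
                cdrs = NULL, rdna = NULL)
  seqs <- character(0)

  if (n > 0) {
    # shared sequence units for the assembly
    hor_unit <- random_dna(config$centromere$monomer_bp *
                             config$centromere$monomers_per_unit)
    rdna_unit <- random_dna(config$rdna$unit_bp)
    hor <- sample_hor_lengths(config, n * 2, seed = seed)
    cdr_len <- sample_cdr_lengths(hor$length_bp, config, seed = seed)
    copies <- rep_len(as.integer(config$rdna$copies), n)

    set.seed(derive_seed(seed, 2L))
    idx <- 0L
    for (hap in haps) {
      for (i in seq_len(n)) {
        idx <- idx + 1L
        nm <- sprintf("chr%d_%s", i, hap)
        L <- if (length(config$chrom_length_bp) == 2) {
          round(runif(1, config$chrom_length_bp[1], config$chrom_length_bp[2]))
        } else config$chrom_length_bp
        built <- build_chromosome(nm, L, hap, config, hor_unit, rdna_unit,
                                  hor$length_bp[idx], hor$component[idx],
                                  cdr_len[idx], copies[i])
        seqs[nm] <- built$seq
        for (tab in TRUTH_TABLES) {
          truth[tab] <- list(rbind(truth[[tab]], built$truth[[tab]]))
        }
      }
    }
  }
  for (tab in TRUTH_TABLES) {
    if (is.null(truth[[tab]])) truth[tab] <- list(data.frame())
    rownames(truth[[tab]]) <- NULL
  }
  out <- list(sequences = Biostrings::DNAStringSet(seqs),
              truth = truth, config = config, seed = as.integer(seed))
  class(out) <- "sim_assembly"
  out
}

# Assemble one chromosome string plus its truth rows. Features are laid out
# in fixed order with the leftover background split evenly between them.
build_chromosome <- function(nm, L, hap, config, hor_unit, rdna_unit,
                             array_len, array_comp, cdr_len, rdna_copies) {
  tel <- config$telomere
  n_copies <- floor(tel$run_bp / 6)
  tel_fwd <- strrep(tel$motif, n_copies)
  tel_rev <- strrep(revcomp(tel$motif), n_copies)

  # feature segments in chromosomal order: name, string, annotations
  feats <- list()
  feats[[length(feats) + 1]] <- list(kind = "tel_p", s = tel_rev)
  if (isTRUE(config$cap$p_arm)) {
    feats[[length(feats) + 1]] <- build_cap(config, "p")
  }
  ar <- build_hor_array(config, hor_unit, array_len, array_comp, cdr_len)
  feats[[length(feats) + 1]] <- ar
  if (rdna_copies > 0) {
    feats[[length(feats) + 1]] <- list(
      kind = "rdna", s = strrep(rdna_unit, rdna_copies), copies = rdna_copies)
  }
  if (isTRUE(config$cap$q_arm)) {
    feats[[length(feats) + 1]] <- build_cap(config, "q")
  }
  feats[[length(feats) + 1]] <- list(kind = "tel_q", s = tel_fwd)

  widths <- vapply(feats, function(f) nchar(f$s), numeric(1))
  n_gaps_between <- length(feats) - 1
  min_margin <- 1000
  leftover <- L - sum(widths)
  if (leftover < n_gaps_between * min_margin) {
    stop(sprintf(
      "chromosome %s too short for configured features: deficit %d bp",
      nm, ceiling(n_gaps_between * min_margin - leftover)))
  }
  # caps sit against their telomere (small fixed margin); the leftover
  # background goes into the interior margins
  kinds <- vapply(feats, function(f) f$kind, character(1))
  tight <- vapply(seq_len(n_gaps_between), function(k) {
    (kinds[k] == "tel_p" && kinds[k + 1] == "cap") ||
      (kinds[k] == "cap" && kinds[k + 1] == "tel_q")
  }, logical(1))
  margins <- rep(min_margin, n_gaps_between)
  spread <- leftover - min_margin * n_gaps_between
  wide <- which(!tight)
  if (!length(wide)) wide <- n_gaps_between
  per <- floor(spread / length(wide))
  margins[wide] <- margins[wide] + per
  margins[wide[length(wide)]] <- margins[wide[length(wide)]] +
    (spread - per * length(wide))

  # optional assembly gaps, carved from the interior margins
  gcfg <- config$gaps
  gap_rows <- NULL
  gap_in_margin <- rep(0L, n_gaps_between)
  if (gcfg$n > 0) {
    ok <- which(margins >= gcfg$length_bp + 2 * 100)
    if (length(ok) < gcfg$n) {
      stop(sprintf("chromosome %s: margins too small for %d gap(s)",
                   nm, gcfg$n))
    }
    gap_in_margin[ok[seq_len(gcfg$n)]] <- 1L
  }

  pieces <- character(0)
  pos <- 0
  truth <- list(chromosomes = data.frame(chrom = nm, haplotype = hap,
                                         length = L),
                telomeres = NULL, gaps = NULL, satellites = NULL,
                arrays = NULL, spacers = NULL, cdrs = NULL, rdna = NULL)
  add <- function(tab, df) truth[[tab]] <<- rbind(truth[[tab]], df)

  for (k in seq_along(feats)) {
    f <- feats[[k]]
    w <- nchar(f$s)
    s0 <- pos
    if (f$kind %in% c("tel_p", "tel_q")) {
      add("telomeres", data.frame(chrom = nm, start = s0, end = s0 + w,
                                  terminus = if (f$kind == "tel_p") "p" else "q"))
      pieces <- c(pieces, f$s)
    } else if (f$kind == "cap") {
      res <- f  # offsets within the cap stored relative; shift by s0
      tr <- res$tracts; tr$start <- tr$start + s0; tr$end <- tr$end + s0
      add("satellites", data.frame(chrom = nm, start = tr$start, end = tr$end,
                                   family = "pCht"))
      if (nrow(res$spacers)) {
        sp <- res$spacers
        sp$start <- sp$start + s0; sp$end <- sp$end + s0
        add("spacers", data.frame(chrom = nm, start = sp$start, end = sp$end,
                                  midpoint = floor((sp$start + sp$end) / 2),
                                  arm = f$arm))
      }
      add("arrays", data.frame(chrom = nm, start = s0, end = s0 + w,
                               family = "pCht", class = "subterminal",
                               arm = f$arm, component = NA_integer_))
      pieces <- c(pieces, f$s)
    } else if (f$kind == "cen") {
      # annotation split into adjacent thirds to exercise array merging
      cut1 <- s0 + floor(w / 3); cut2 <- s0 + floor(2 * w / 3)
      add("satellites", data.frame(
        chrom = nm, start = c(s0, cut1, cut2), end = c(cut1, cut2, s0 + w),
        family = "alphasat_SF1"))
      add("arrays", data.frame(chrom = nm, start = s0, end = s0 + w,
                               family = "alphasat_SF1",
                               class = "centromeric_hor", arm = "unknown",
                               component = f$component))
      c0 <- s0 + floor((w - f$cdr_len) / 2)
      add("cdrs", data.frame(chrom = nm, start = c0, end = c0 + f$cdr_len))
      pieces <- c(pieces, f$s)
    } else if (f$kind == "rdna") {
      add("satellites", data.frame(chrom = nm, start = s0, end = s0 + w,
                                   family = "rDNA"))
      add("arrays", data.frame(chrom = nm, start = s0, end = s0 + w,
                               family = "rDNA", class = "rdna",
                               arm = "unknown", component = NA_integer_))
      add("rdna", data.frame(chrom = nm, haplotype = hap, span_bp = w,
                             unit_bp = config$rdna$unit_bp,
                             copies = f$copies))
      pieces <- c(pieces, f$s)
    }
    pos <- pos + w
    if (k < length(feats)) {
      mw <- margins[k]
      if (gap_in_margin[k]) {
        gl <- gcfg$length_bp
        pre <- floor((mw - gl) / 2)
        gs <- pos + pre
        add("gaps", data.frame(chrom = nm, start = gs, end = gs + gl))
        pieces <- c(pieces, random_dna(pre), strrep("N", gl),
                    random_dna(mw - pre - gl))
      } else {
        pieces <- c(pieces, random_dna(mw))
      }
      pos <- pos + mw
    }
  }
  if (!is.null(truth$arrays)) {
    truth$arrays$array_id <- sprintf("%s_%s_%d", nm, truth$arrays$class,
                                     seq_len(nrow(truth$arrays)))
    if (!is.null(truth$cdrs) && nrow(truth$cdrs)) {
      cen_id <- truth$arrays$array_id[truth$arrays$class == "centromeric_hor"]
      truth$cdrs$array_id <- rep_len(cen_id, nrow(truth$cdrs))
    }
  }
  list(seq = paste(pieces, collapse = ""), truth = truth)
}

build_hor_array <- function(config, unit, array_len, comp, cdr_len) {
  n_units <- ceiling(array_len / nchar(unit))
  s <- substr(strrep(unit, n_units), 1, array_len)
  s <- mutate_dna(s, config$centromere$substitution_rate)
  list(kind = "cen", s = s, component = comp, cdr_len = cdr_len)
}

# A cap: n_tracts satellite tracts separated by (n_tracts - 1) random-DNA
# spacers of fixed length. Offsets in the returned tables are cap-relative.
build_cap <- function(config, arm) {
  cp <- config$cap
  tl <- pmax(round(rnorm(cp$n_tracts, cp$tract_mean_bp, cp$tract_sd_bp)), 1000)
  mono <- cp$monomer
  pieces <- character(0)
  tracts <- NULL; spacers <- NULL
  pos <- 0
  for (j in seq_len(cp$n_tracts)) {
    s <- substr(strrep(mono, ceiling(tl[j] / nchar(mono))), 1, tl[j])
    tracts <- rbind(tracts, data.frame(start = pos, end = pos + tl[j]))
    pieces <- c(pieces, s)
    pos <- pos + tl[j]
    if (j < cp$n_tracts) {
      spacers <- rbind(spacers, data.frame(start = pos, end = pos + cp$spacer_bp))
      pieces <- c(pieces, random_dna(cp$spacer_bp))
      pos <- pos + cp$spacer_bp
    }
  }
  list(kind = "cap", s = paste(pieces, collapse = ""), arm = arm,
       tracts = tracts,
       spacers = if (is.null(spacers)) data.frame(start = numeric(),
                                                  end = numeric()) else spacers)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write a synthetic assembly to disk
#'
#' One FASTA per haplotype (60-column wrap, gaps as N) plus truth BED/TSV
#' tables.
#'
#' @param sim a `sim_assembly` from [generate_assembly()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_assembly <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (hap in c("h1", "h2")) {
    sel <- grepl(paste0("_", hap, "$"), names(sim$sequences))
    p <- file.path(outdir, paste0("assembly_", hap, ".fa"))
    Biostrings::writeXStringSet(sim$sequences[sel], p, width = 60)
    paths[paste0("fasta_", hap)] <- p
  }
  bed4 <- function(df, cols, p) {
    if (nrow(df)) write_bed(df[, cols], p) else file.create(p)
    p
  }
  tt <- sim$truth
  paths["telomeres"] <- bed4(tt$telomeres,
                             c("chrom", "start", "end", "terminus"),
                             file.path(outdir, "truth_telomeres.bed"))
  paths["gaps"] <- bed4(tt$gaps, c("chrom", "start", "end"),
                        file.path(outdir, "truth_gaps.bed"))
  paths["satellites"] <- bed4(tt$satellites,
                              c("chrom", "start", "end", "family"),
                              file.path(outdir, "truth_satellites.bed"))
  paths["arrays"] <- bed4(tt$arrays,
                          c("chrom", "start", "end", "family", "class", "arm"),
                          file.path(outdir, "truth_arrays.bed"))
  paths["spacers"] <- bed4(tt$spacers, c("chrom", "start", "end"),
                           file.path(outdir, "truth_spacers.bed"))
  paths["cdrs"] <- bed4(tt$cdrs, c("chrom", "start", "end"),
                        file.path(outdir, "truth_cdrs.bed"))
  p <- file.path(outdir, "truth_rdna.tsv")
  utils::write.table(tt$rdna, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["rdna"] <- p
  invisible(paths)
}

#' Generate a per-CpG methylation track for a synthetic assembly
#'
#' Emits one record at the C of every CG dinucleotide (forward strand) of
#' every generated sequence. Fractions are Gaussian draws around the
#' background mean, except inside truth CDRs (CDR mean) and truth spacer
#' intervals (pocket mean); all clamped to \[0, 1\]. Coverage is Poisson.
#'
#' @param sim a `sim_assembly` from [generate_assembly()].
#' @param seed integer seed.
#' @return a methylation track data.frame (`chrom`, `start`, `end`,
#'   `coverage`, `fraction`), sorted.
#' @export
generate_methylation <- function(sim, seed = sim$config$seed) {
  set.seed(derive_seed(seed, 3L))
  m <- sim$config$methylation
  out <- vector("list", length(sim$sequences))
  for (i in seq_along(sim$sequences)) {
    nm <- names(sim$sequences)[i]
    cpg <- Biostrings::start(
      Biostrings::matchPattern("CG", sim$sequences[[i]])) - 1L
    if (!length(cpg)) {
      warning(sprintf("no CpG sites on %s; emitting empty track", nm))
      next
    }
    frac <- rnorm(length(cpg), m$background_mean, m$background_sd)
    frac <- set_region_means(frac, cpg, sim$truth$cdrs, nm, m$cdr_mean,
                             m$background_sd)
    frac <- set_region_means(frac, cpg, sim$truth$spacers, nm, m$pocket_mean,
                             m$background_sd)
    out[[i]] <- data.frame(chrom = nm, start = cpg, end = cpg + 2L,
                           coverage = rpois(length(cpg), m$coverage),
                           fraction = pmin(pmax(frac, 0), 1))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      coverage = integer(), fraction = numeric())
  }
  validate_track(out)
}

set_region_means <- function(frac, cpg, regions, nm, mean_value, sd_value) {
  if (is.null(regions) || !nrow(regions)) return(frac)
  r <- regions[regions$chrom == nm, , drop = FALSE]
  for (j in seq_len(nrow(r))) {
    k <- cpg >= r$start[j] & cpg < r$end[j]
    frac[k] <- rnorm(sum(k), mean_value, sd_value)
  }
  frac
}

#' Default ape species tree with speciation times in Ma
#'
#' Rooted binary tree over the six sequenced non-human apes (chimpanzee,
#' bonobo, gorilla, Bornean and Sumatran orangutans, siamang), with node
#' depths at the Pan split (1.7 Ma), the gorilla split (10.75 Ma), the
#' orangutan split (19 Ma), the Pongo split (0.9 Ma), and the siamang root
#' (20 Ma). `include_human = TRUE` inserts human as sister to Pan at 6 Ma.
#'
#' @param include_human logical.
#' @return an [ape::phylo] tree with branch lengths in Ma and named
#'   internal nodes.
#' @export
ape_species_tree <- function(include_human = FALSE) {
  pan <- "(chimpanzee:1.7,bonobo:1.7)pan_ancestor"
  inner <- if (include_human) {
    paste0("((", pan, ":4.3,human:6)homininae_ancestor:4.75,gorilla:10.75)")
  } else {
    paste0("((", pan, ":9.05,gorilla:10.75)")
  }
  txt <- paste0(
    "(", inner, "african_ape_ancestor:8.25,",
    "(bornean_orangutan:0.9,sumatran_orangutan:0.9)pongo_ancestor:18.1)",
    "great_ape_ancestor:1,siamang:20)root;")
  ape::read.tree(text = txt)
}

# Tip labels of the clade under `node` (a node index of the phylo tree).
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- tree$node.label
  if (is.null(nn) || !length(nn)) {
    nn <- paste0("node", seq_len(tree$Nnode) + ntip)
  }
  nn[nn == ""] <- paste0("node", which(nn == "") + ntip)
  c(tree$tip.label, nn)
}

#' Simulate inversions evolving on a species tree
#'
#' Places a Poisson number of events (`rate_per_ma` x total branch length)
#' on branches with probability proportional to branch length; a configured
#' fraction is recurrent and gets a second, clade-disjoint branch. Leaf
#' genotypes are the presence/absence implied by the branch(es). Events get
#' reference-coordinate intervals (`chr1..chrN` of the configured lengths).
#'
#' @param tree rooted [ape::phylo] with branch lengths in Ma.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `genotypes` (data.frame: event_id, chrom, start, end,
#'   one `inv`/`ref` column per leaf) and `truth` (event_id, branch,
#'   branch2, recurrent). Branches are named by their child node.
#' @export
simulate_inversions_on_tree <- function(tree, config, seed = config$seed) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    stop("zero-length tree: branch lengths in Ma are required")
  }
  set.seed(derive_seed(seed, 4L))
  inv <- config$inversion
  leaves <- tree$tip.label
  nms <- node_names(tree)
  n_events <- rpois(1, inv$rate_per_ma * sum(tree$edge.length))
  geno_cols <- function(present) {
    stats::setNames(as.list(ifelse(leaves %in% present, "inv", "ref")), leaves)
  }
  genotypes <- NULL; truth <- NULL
  chrom_lengths <- rep_len(
    if (length(config$chrom_length_bp) == 2) mean(config$chrom_length_bp)
    else config$chrom_length_bp,
    max(config$n_chromosomes, 1))
  edge_clades <- lapply(tree$edge[, 2], clade_tips, tree = tree)
  for (e in seq_len(n_events)) {
    b1 <- sample.int(nrow(tree$edge), 1, prob = tree$edge.length)
    present <- edge_clades[[b1]]
    b2 <- NA_integer_
    recurrent <- runif(1) < inv$recurrent_fraction
    if (recurrent) {
      # a genuinely homoplastic second branch: clade-disjoint from the
      # first and whose union with it is not itself a clade (otherwise the
      # two gains would be indistinguishable from one ancestral gain)
      ok <- which(vapply(seq_along(edge_clades), function(j) {
        cl <- edge_clades[[j]]
        if (any(cl %in% edge_clades[[b1]])) return(FALSE)
        u <- sort(c(cl, edge_clades[[b1]]))
        !any(vapply(edge_clades, function(x) identical(sort(x), u),
                    logical(1)))
      }, logical(1)))
      if (!length(ok)) {
        recurrent <- FALSE
      } else {
        b2 <- if (length(ok) == 1) ok else sample(ok, 1)
        present <- c(present, edge_clades[[b2]])
      }
    }
    ci <- sample.int(length(chrom_lengths), 1)
    len <- round(runif(1, inv$size_range_bp[1], inv$size_range_bp[2]))
    start <- floor(runif(1, 0, chrom_lengths[ci] - len))
    genotypes <- rbind(genotypes, data.frame(
      event_id = sprintf("inv%04d", e), chrom = paste0("chr", ci),
      start = start, end = start + len, geno_cols(present),
      check.names = FALSE))
    truth <- rbind(truth, data.frame(
      event_id = sprintf("inv%04d", e),
      branch = nms[tree$edge[b1, 2]],
      branch2 = if (recurrent) nms[tree$edge[b2, 2]] else NA_character_,
      recurrent = recurrent))
  }
  if (is.null(genotypes)) {
    genotypes <- data.frame(event_id = character(), chrom = character(),
                            start = numeric(), end = numeric())
    for (l in leaves) genotypes[[l]] <- character()
    truth <- data.frame(event_id = character(), branch = character(),
                        branch2 = character(), recurrent = logical())
  }
  list(genotypes = genotypes, truth = truth)
}
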