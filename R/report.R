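# End-to-end pipeline driver and Table-style reporting.

#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param seed integer seed governing all stage randomness.
#' @param sim a [sim_config()] describing the synthetic input genome.
#' @param stages subset of `c("simulate", "qc", "arrays", "cdr", "caps",
#'   "rdna", "inversions")`; outputs are written only for requested stages.
#' @param tree species tree for the inversions stage (default
#'   [ape_species_tree()]).
#' @param params named list of parameter overrides for downstream stages
#'   (recognised: `end_window_bp`, `max_gap_bp`, `min_array_bp`,
#'   `cdr_window_bp`, `cdr_step_bp`, `cdr_drop`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = sim_config(seed = seed),
                            stages = c("simulate", "qc", "arrays", "cdr",
                                       "caps", "rdna", "inversions"),
                            tree = ape_species_tree(), params = list()) {
  known <- c("simulate", "qc", "arrays", "cdr", "caps", "rdna", "inversions")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defaults <- list(end_window_bp = 5e5, max_gap_bp = 1e4, min_array_bp = 1e4,
                   cdr_window_bp = 5000, cdr_step_bp = 1000, cdr_drop = 0.2)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  out <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              stages = stages, tree = tree,
              params = utils::modifyList(defaults, params))
  class(out) <- "pipeline_config"
  out
}

#' Run the analysis pipeline on a synthetic genome
#'
#' Generates the configured synthetic assembly and runs the requested
#' stages (assembly QC, satellite arrays, CDR calling, subterminal caps,
#' rDNA accounting, inversion phylogenetics), writing per-stage TSV/BED/
#' JSON outputs plus a manifest listing every output file with its MD5
#' checksum. Deterministic for identical config + seed.
#'
#' @param config a [pipeline_config()].
#' @return list: `manifest` (data.frame file/md5), `results` (per-stage
#'   result objects), invisibly the manifest path in `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pr <- config$params
  written <- character(0)
  results <- list()
  emit <- function(path) written <<- c(written, path)

  sim <- generate_assembly(config$sim, seed = config$seed)
  meth <- generate_methylation(sim, seed = config$seed)

  if ("simulate" %in% config$stages) {
    paths <- write_assembly(sim, file.path(config$outdir, "simulate"))
    for (p in paths) emit(p)
    mp <- file.path(config$outdir, "simulate", "methylation.tsv")
    write_methylation(meth, mp); emit(mp)
  }

  chrom_lengths <- stats::setNames(sim$truth$chromosomes$length,
                                   sim$truth$chromosomes$chrom)

  if ("qc" %in% config$stages) {
    rdna_by_chrom <- split(sim$truth$arrays[sim$truth$arrays$class == "rdna",
                                            c("start", "end")],
                           sim$truth$arrays$chrom[sim$truth$arrays$class ==
                                                    "rdna"])
    records <- lapply(names(sim$sequences), function(nm) {
      chromosome_record_from_sequence(
        nm, sim$sequences[[nm]], rdna = rdna_by_chrom[[nm]],
        motif = config$sim$telomere$motif)
    })
    qc <- qc_assembly(records)
    results$qc <- qc
    p <- file.path(config$outdir, "qc_per_chromosome.tsv")
    utils::write.table(qc$per_chromosome, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
    p <- file.path(config$outdir, "qc_summary.tsv")
    utils::write.table(qc$summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
  }

  arrays <- NULL
  if (any(c("arrays", "cdr", "caps", "rdna") %in% config$stages)) {
    arrays <- merge_to_arrays(sim$truth$satellites,
                              max_gap_bp = pr$max_gap_bp,
                              min_array_bp = pr$min_array_bp)
    arrays <- classify_arrays(arrays, chrom_lengths,
                              end_window_bp = pr$end_window_bp)
    arrays$array_id <- sprintf("%s_%s_%d", arrays$chrom, arrays$class,
                               stats::ave(seq_len(nrow(arrays)),
                                          arrays$chrom, arrays$class,
                                          FUN = seq_along))
  }
  if ("arrays" %in% config$stages) {
    results$arrays <- arrays
    p <- file.path(config$outdir, "arrays.bed")
    write_bed(arrays[, c("chrom", "start", "end", "family", "class", "arm")],
              p); emit(p)
    cen <- arrays[arrays$class == "centromeric_hor", , drop = FALSE]
    part <- minicentromere_partition(cen$end - cen$start)
    results$minicentromeres <- part
    p <- file.path(config$outdir, "minicentromeres.json")
    jsonlite::write_json(list(n_mini = length(part$mini),
                              n_normal = length(part$normal)),
                         p, auto_unbox = TRUE); emit(p)
  }

  if ("cdr" %in% config$stages) {
    cen <- arrays[arrays$class == "centromeric_hor", , drop = FALSE]
    cdrs <- do.call(rbind, lapply(seq_len(nrow(cen)), function(i) {
      call_cdrs(meth, cen[i, ], window_bp = pr$cdr_window_bp,
                step_bp = pr$cdr_step_bp, drop = pr$cdr_drop)
    }))
    results$cdrs <- cdrs
    p <- file.path(config$outdir, "cdrs.bed")
    if (!is.null(cdrs) && nrow(cdrs)) {
      write_bed(cdrs[, c("chrom", "start", "end", "array_id")], p)
    } else file.create(p)
    emit(p)
    if (nrow(cen) >= 3 && stats::var(cen$end - cen$start) > 0) {
      tot <- vapply(cen$array_id, function(id) {
        sum(cdrs$end[cdrs$array_id == id] - cdrs$start[cdrs$array_id == id])
      }, numeric(1))
      reg <- cdr_length_vs_array_regression(data.frame(
        array_length_bp = cen$end - cen$start, cdr_length_bp = tot))
      results$cdr_regression <- reg
      p <- file.path(config$outdir, "cdr_regression.json")
      jsonlite::write_json(reg[c("slope", "intercept", "r_squared", "n")],
                           p, auto_unbox = TRUE, digits = NA); emit(p)
    }
  }

  if ("caps" %in% config$stages) {
    caps <- detect_caps(arrays, chrom_lengths)
    results$caps <- caps
    p <- file.path(config$outdir, "caps.bed")
    if (nrow(caps)) write_bed(caps) else file.create(p)
    emit(p)
    all_spacers <- NULL
    for (i in seq_len(nrow(caps))) {
      fs <- find_spacers(caps[i, ], sim$truth$satellites)
      if (nrow(fs$spacers)) {
        sp <- fs$spacers
        sp$cap <- sprintf("%s_%s", caps$chrom[i], caps$arm[i])
        sp$modal_length_bp <- fs$modal_length_bp
        all_spacers <- rbind(all_spacers, sp)
      }
    }
    results$spacers <- all_spacers
    p <- file.path(config$outdir, "spacers.bed")
    if (!is.null(all_spacers)) {
      write_bed(all_spacers[, c("chrom", "start", "end", "midpoint")], p)
    } else file.create(p)
    emit(p)
    if (!is.null(all_spacers) && nrow(all_spacers)) {
      prof <- spacer_methylation_profile(all_spacers, meth)
      results$spacer_profile <- prof
      p <- file.path(config$outdir, "spacer_profile.tsv")
      utils::write.table(prof$profile, p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
      p <- file.path(config$outdir, "pocket_statistic.json")
      jsonlite::write_json(prof[c("pocket_statistic", "p_value", "n_inside",
                                  "n_flank")],
                           p, auto_unbox = TRUE, digits = NA); emit(p)
    }
  }

  if ("rdna" %in% config$stages) {
    rd <- arrays[arrays$class == "rdna", , drop = FALSE]
    rd$haplotype <- sub("^.*_(h[12])$", "\\1", rd$chrom)
    rd$copies <- count_rdna_units(rd$end - rd$start,
                                  config$sim$rdna$unit_bp)
    totals <- total_rdna(rd, "haplotype")
    results$rdna <- list(arrays = rd, totals = totals,
                         diploid = total_rdna(rd, "diploid"))
    p <- file.path(config$outdir, "rdna_totals.tsv")
    utils::write.table(totals, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
  }

  if ("inversions" %in% config$stages) {
    if (is.null(config$tree)) {
      stop("stage 'inversions' requires a species tree input")
    }
    invs <- simulate_inversions_on_tree(config$tree, config$sim,
                                        seed = config$seed)
    assign <- assign_inversions(invs$genotypes, config$tree)
    results$inversions <- list(simulated = invs, assigned = assign)
    p <- file.path(config$outdir, "inversion_assignments.tsv")
    utils::write.table(assign, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
  }

  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(written)))
  mp <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, dataframe = "rows")
  list(manifest = manifest, manifest_path = mp, results = results)
}

#' Table-style assembly summary with an Average row
#'
#' Emits the per-assembly QC columns plus an arithmetic-mean Average row
#' rounded at the printed precision (see [summarize_assemblies()]).
#'
#' @param per_assembly data.frame with an `assembly` label column and any
#'   of `total_bases_gb`, `contig_n50_mb`, `n_t2t`, `n_issues`, `qv`.
#' @param path optional TSV output path.
#' @return data.frame with the Average row appended.
#' @export
table1_report <- function(per_assembly, path = NULL) {
  stopifnot(is.data.frame(per_assembly), nrow(per_assembly) >= 1)
  avg <- summarize_assemblies(per_assembly)
  row <- per_assembly[1, , drop = FALSE]
  for (cn in names(row)) row[[cn]] <- NA
  if ("assembly" %in% names(row)) row$assembly <- "Average"
  for (cn in names(avg)) row[[cn]] <- avg[[cn]]
  out <- rbind(per_assembly, row)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
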