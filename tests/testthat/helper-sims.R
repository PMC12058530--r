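# Shared synthetic fixtures, generated once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) assign(key, maker(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# A compact diploid genome exercising every feature class: 2 x 4 Mb
# chromosomes per haplotype, ~800 kb centromeric arrays, p-arm caps of four
# ~200 kb tracts with 34 kb spacers, a 5-unit rDNA array on chr1.
small_config <- function() {
  sim_config(
    n_chromosomes = 2, chrom_length_bp = 4e6,
    centromere = list(distribution = "unimodal", mean_bp = 8e5, sdlog = 0.2,
                      range_bp = list(c(3e5, 1.5e6))),
    cap = list(n_tracts = 4, tract_mean_bp = 2e5, tract_sd_bp = 2e4,
               spacer_bp = 34000),
    rdna = list(copies = c(5L, 0L)),
    seed = 2)
}

small_sim <- function() {
  cached("small_sim", function() generate_assembly(small_config(), seed = 2))
}

small_meth <- function() {
  cached("small_meth", function() generate_methylation(small_sim(), seed = 2))
}

small_arrays <- function() {
  cached("small_arrays", function() {
    sim <- small_sim()
    classify_arrays(merge_to_arrays(sim$truth$satellites), chrom_lengths(sim))
  })
}

chrom_lengths <- function(sim) {
  stats::setNames(sim$truth$chromosomes$length, sim$truth$chromosomes$chrom)
}

# Minimal fast genome: no caps, tiny centromeres, no rDNA.
tiny_config <- function(n_chromosomes = 1, seed = 5, ...) {
  sim_config(
    n_chromosomes = n_chromosomes, chrom_length_bp = 4e5,
    telomere = list(run_bp = 5000),
    centromere = list(distribution = "unimodal", mean_bp = 5e4, sdlog = 0.2,
                      range_bp = list(c(3e4, 8e4))),
    cap = list(p_arm = FALSE),
    rdna = list(copies = 0L),
    seed = seed, ...)
}
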