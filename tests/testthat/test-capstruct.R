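test_that("cap detection requires subterminal anchors and spans the chain", {
  lens <- c(c1 = 10e6)
  none <- classify_arrays(
    data.frame(chrom = "c1", start = 5e6, end = 5.5e6,
               family = "alphasat_SF1"), lens)
  expect_equal(nrow(detect_caps(none, lens)), 0)

  sim <- small_sim()
  arr <- small_arrays()
  caps <- detect_caps(arr, chrom_lengths(sim))
  truth_caps <- sim$truth$arrays[sim$truth$arrays$class == "subterminal", ]
  expect_equal(nrow(caps), nrow(truth_caps))
  key <- function(d) sort(paste(d$chrom, d$start, d$end))
  expect_equal(key(caps), key(truth_caps))
  expect_true(all(caps$arm == "p"))
})

test_that("caps on both arms are detected with their arms", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 6e6,
    centromere = list(distribution = "unimodal", mean_bp = 5e5, sdlog = 0.1,
                      range_bp = list(c(3e5, 8e5))),
    cap = list(p_arm = TRUE, q_arm = TRUE, n_tracts = 3,
               tract_mean_bp = 2e5, tract_sd_bp = 1e4, spacer_bp = 32000),
    rdna = list(copies = 0L), seed = 6)
  sim <- generate_assembly(cfg, seed = 6)
  arr <- classify_arrays(merge_to_arrays(sim$truth$satellites),
                         chrom_lengths(sim))
  caps <- detect_caps(arr, chrom_lengths(sim))
  per_chrom <- split(caps$arm, caps$chrom)
  for (arms in per_chrom) expect_setequal(arms, c("p", "q"))
})

test_that("spacers are the annotation gaps, with exact modal length", {
  # fully covered cap: no spacers
  ann <- data.frame(chrom = "c1", start = c(0, 5e5), end = c(5e5, 1e6),
                    family = "pCht")
  fs <- find_spacers(list(chrom = "c1", start = 0, end = 1e6), ann)
  expect_equal(nrow(fs$spacers), 0)
  expect_true(is.na(fs$modal_length_bp))

  sim <- small_sim()
  arr <- small_arrays()
  caps <- detect_caps(arr, chrom_lengths(sim))
  cap1 <- caps[1, ]
  fs <- find_spacers(cap1, sim$truth$satellites)
  truth_sp <- sim$truth$spacers[sim$truth$spacers$chrom == cap1$chrom, ]
  expect_equal(nrow(fs$spacers), nrow(truth_sp))
  expect_equal(fs$spacers$start, truth_sp$start)
  expect_equal(fs$spacers$end, truth_sp$end)
  expect_equal(fs$modal_length_bp, 34000)

  # majority bin wins; ties break toward the smaller bin
  mk <- function(lens) {
    pos <- cumsum(c(0, rbind(4e5, lens)))
    tr <- data.frame(start = pos[seq(1, length(pos) - 1, by = 2)])
    tr$end <- tr$start + 4e5
    data.frame(chrom = "c1", start = tr$start, end = tr$end, family = "pCht")
  }
  ann2 <- mk(c(32000, 32000, 57000))
  fs2 <- find_spacers(list(chrom = "c1", start = 0,
                           end = max(ann2$end)), ann2)
  expect_equal(fs2$modal_length_bp, 32000)
  ann3 <- mk(c(32000, 57000))
  fs3 <- find_spacers(list(chrom = "c1", start = 0,
                           end = max(ann3$end)), ann3)
  expect_equal(fs3$modal_length_bp, 32000)
})

test_that("tract statistics recover configured lengths and periodicity", {
  single <- tract_stats(data.frame(start = 0, end = 1e5),
                        data.frame(start = numeric(), end = numeric(),
                                   midpoint = numeric()))
  expect_true(is.na(single$mean_spacing_bp))
  expect_true(is.na(single$tract_sd_bp))

  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 13e6,
    centromere = list(distribution = "unimodal", mean_bp = 4e5, sdlog = 0.1,
                      range_bp = list(c(2e5, 6e5))),
    cap = list(n_tracts = 10, tract_mean_bp = 5e5, tract_sd_bp = 5e4,
               spacer_bp = 34000),
    rdna = list(copies = 0L), seed = 2)
  sim <- generate_assembly(cfg, seed = 2)
  arr <- classify_arrays(merge_to_arrays(sim$truth$satellites),
                         chrom_lengths(sim))
  caps <- detect_caps(arr, chrom_lengths(sim))
  tl <- sl <- c()
  for (i in seq_len(nrow(caps))) {
    fs <- find_spacers(caps[i, ], sim$truth$satellites)
    st <- tract_stats(fs$tracts, fs$spacers)
    tl <- c(tl, st$tract_mean_bp)
    sl <- c(sl, st$mean_spacing_bp)
  }
  # 20 tracts across two haplotypes: mean within 2 sd / sqrt(n) of 500 kb
  expect_lt(abs(mean(tl) - 5e5), 2 * 5e4 / sqrt(20))
})

test_that("spacer periodicity recovers a 750 kb period within 5%", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 7e6,
    centromere = list(distribution = "unimodal", mean_bp = 4e5, sdlog = 0.1,
                      range_bp = list(c(2e5, 6e5))),
    cap = list(n_tracts = 6, period_bp = 750000, tract_sd_bp = 5000,
               spacer_bp = 34000),
    rdna = list(copies = 0L), seed = 11)
  expect_equal(cfg$cap$tract_mean_bp, 750000 - 34000)
  sim <- generate_assembly(cfg, seed = 11)
  arr <- classify_arrays(merge_to_arrays(sim$truth$satellites),
                         chrom_lengths(sim))
  caps <- detect_caps(arr, chrom_lengths(sim))
  sp <- c()
  for (i in seq_len(nrow(caps))) {
    fs <- find_spacers(caps[i, ], sim$truth$satellites)
    sp <- c(sp, tract_stats(fs$tracts, fs$spacers)$mean_spacing_bp)
  }
  expect_lt(abs(mean(sp) - 750000) / 750000, 0.05)
})

test_that("cap bookkeeping partitions exactly into tracts, spacers, margins", {
  sim <- small_sim()
  arr <- small_arrays()
  caps <- detect_caps(arr, chrom_lengths(sim))
  for (i in seq_len(nrow(caps))) {
    fs <- find_spacers(caps[i, ], sim$truth$satellites)
    part <- cap_partition(caps[i, ], fs$tracts, fs$spacers)
    expect_equal(part$tract_bp + part$spacer_bp + part$margin_bp,
                 part$cap_bp)
    expect_equal(part$margin_bp, 0) # noise-free synthetic caps have none
  }
})

test_that("spacer profiles show the hypomethylated pocket", {
  sim <- small_sim()
  meth <- small_meth()
  sp <- sim$truth$spacers
  prof <- spacer_methylation_profile(sp, meth)
  expect_equal(prof$pocket_statistic, -0.8, tolerance = 0.05)
  expect_lt(prof$p_value, 0.001)
  # profile symmetry for symmetric spacer placement
  p <- prof$profile
  left <- p$mean_fraction[p$offset < -1000]
  right <- rev(p$mean_fraction[p$offset >= 500])[seq_along(left)]
  expect_lt(abs(mean(left) - mean(right)), 0.05)

  # uniform methylation: statistic near zero, two-sided-neutral p
  flat <- meth
  set.seed(1)
  flat$fraction <- pmin(pmax(rnorm(nrow(flat), 0.9, 0.05), 0), 1)
  prof0 <- spacer_methylation_profile(sp[1:3, ], flat)
  expect_lt(abs(prof0$pocket_statistic), 0.01)
  expect_gt(prof0$p_value, 0.05)

  # single spacer: mean defined, sd missing where a bin has one value
  prof1 <- spacer_methylation_profile(sp[1, ], meth)
  expect_true(all(is.finite(prof1$profile$mean_fraction)))

  expect_error(spacer_methylation_profile(sp[1, ], meth[0, ]), "no CpGs")
})
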