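# Build a regular synthetic track: CpGs every `spacing` bp over [0, len).
flat_track <- function(len, fraction = 0.9, spacing = 50, chrom = "c1") {
  pos <- seq(0, len - 2, by = spacing)
  data.frame(chrom = chrom, start = pos, end = pos + 2,
             coverage = 30, fraction = fraction)
}

test_that("windowed means average CpGs and flag empty windows", {
  tr <- flat_track(1e5)
  region <- list(chrom = "c1", start = 0, end = 1e5)
  b <- binned_methylation(tr, region, window_bp = 5000, step_bp = 1000)
  expect_true(all(abs(b$mean_fraction[!is.na(b$mean_fraction)] - 0.9) < 1e-12))

  none <- binned_methylation(tr[0, ], region, window_bp = 5000,
                             step_bp = 5000)
  expect_true(all(is.na(none$mean_fraction)))
  expect_true(all(none$n_cpg == 0))

  three <- data.frame(chrom = "c1", start = c(10, 20, 30), end = c(12, 22, 32),
                      coverage = 1, fraction = c(0.2, 0.4, 0.9))
  b3 <- binned_methylation(three, list(chrom = "c1", start = 0, end = 100),
                           window_bp = 100, step_bp = 100)
  expect_equal(b3$mean_fraction, 0.5)
  expect_equal(b3$n_cpg, 3L)
})

test_that("overlapping windows count each CpG in every covering window", {
  tr <- data.frame(chrom = "c1", start = 2500, end = 2502, coverage = 1,
                   fraction = 0.5)
  b <- binned_methylation(tr, list(chrom = "c1", start = 0, end = 10000),
                          window_bp = 2000, step_bp = 1000)
  covered <- which(b$n_cpg == 1)
  expect_equal(b$start[covered], c(1000, 2000))
})

test_that("CDR calling recovers an embedded dip and ignores flat signal", {
  expect_equal(nrow(call_cdrs(flat_track(5e6),
                              list(chrom = "c1", start = 0, end = 5e6))), 0)

  tr <- flat_track(5e6)
  dip <- tr$start >= 2e6 & tr$start < 2e6 + 5e4
  tr$fraction[dip] <- 0.1
  cdrs <- call_cdrs(tr, list(chrom = "c1", start = 0, end = 5e6,
                             array_id = "a1"))
  expect_equal(nrow(cdrs), 1)
  expect_gte(jaccard(cdrs$start, cdrs$end, 2e6, 2e6 + 5e4), 0.9)
  expect_lt(cdrs$mean_inside, cdrs$mean_flanking)

  # an entirely hypomethylated array has no dip relative to its own baseline
  expect_equal(nrow(call_cdrs(flat_track(5e6, fraction = 0.1),
                              list(chrom = "c1", start = 0, end = 5e6))), 0)

  # no CpGs at all: empty result with a warning
  expect_warning(
    out <- call_cdrs(flat_track(1e5)[0, ],
                     list(chrom = "c1", start = 0, end = 1e5)),
    "no CpGs")
  expect_equal(nrow(out), 0)
})

test_that("called CDRs stay inside the array and never overlap", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- flat_track(2e6)
    tr$fraction <- pmin(pmax(rnorm(nrow(tr), 0.85, 0.1), 0), 1)
    n_dips <- sample(1:3, 1)
    for (d in seq_len(n_dips)) {
      s <- sample.int(1.8e6, 1)
      k <- tr$start >= s & tr$start < s + 3e4
      tr$fraction[k] <- 0.05
    }
    arr <- list(chrom = "c1", start = 0, end = 2e6)
    cdrs <- call_cdrs(tr, arr)
    if (!nrow(cdrs)) next
    expect_true(all(cdrs$start >= arr$start & cdrs$end <= arr$end))
    cdrs <- cdrs[order(cdrs$start), ]
    if (nrow(cdrs) > 1) {
      expect_true(all(cdrs$start[-1] >= cdrs$end[-nrow(cdrs)]))
    }
    expect_true(all(cdrs$mean_inside < cdrs$mean_flanking))
  }
})

test_that("synthetic truth CDRs are recovered with high Jaccard", {
  sim <- small_sim()
  meth <- small_meth()
  arrays <- sim$truth$arrays[sim$truth$arrays$class == "centromeric_hor", ]
  for (i in seq_len(nrow(arrays))) {
    truth <- sim$truth$cdrs[sim$truth$cdrs$array_id == arrays$array_id[i], ]
    if (truth$end - truth$start < 3 * 5000) next
    cdrs <- call_cdrs(meth, arrays[i, ])
    expect_equal(nrow(cdrs), 1)
    expect_gte(jaccard(cdrs$start, cdrs$end, truth$start, truth$end), 0.9)
  }
})

test_that("the CDR-vs-array regression matches closed-form least squares", {
  exact <- data.frame(array_length_bp = 1:5, cdr_length_bp = 1:5)
  expect_equal(cdr_length_vs_array_regression(exact)$r_squared, 1)

  const <- data.frame(array_length_bp = 1:5, cdr_length_bp = rep(2, 5))
  expect_equal(cdr_length_vs_array_regression(const)$r_squared, 0)

  hand <- data.frame(array_length_bp = c(1, 2, 3, 4),
                     cdr_length_bp = c(2, 3, 5, 4))
  fit <- cdr_length_vs_array_regression(hand)
  expect_equal(fit$slope, 0.8)
  expect_equal(fit$intercept, 1.5)
  expect_equal(fit$r_squared, 1 - 1.8 / 5)

  degen <- data.frame(array_length_bp = rep(3, 4), cdr_length_bp = 1:4)
  expect_error(cdr_length_vs_array_regression(degen), "degenerate")
})

test_that("R-squared is invariant to affine rescaling of both variables", {
  set.seed(3)
  d <- data.frame(array_length_bp = runif(20, 1e5, 5e6))
  d$cdr_length_bp <- 0.3 * d$array_length_bp + rnorm(20, 0, 2e5)
  r2 <- cdr_length_vs_array_regression(d)$r_squared
  d2 <- data.frame(array_length_bp = 3.7 * d$array_length_bp - 500,
                   cdr_length_bp = 0.002 * d$cdr_length_bp + 11)
  expect_equal(cdr_length_vs_array_regression(d2)$r_squared, r2)
})
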