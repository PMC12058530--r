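ape6 <- ape_species_tree()
leaves <- ape6$tip.label

pres <- function(present) {
  stats::setNames(leaves %in% present, leaves)
}

test_that("single-origin characters map to their branch", {
  sia <- fitch_assign(pres("siamang"), ape6)
  expect_equal(sia$changes, 1)
  expect_equal(sia$branch, "siamang")

  pan <- fitch_assign(pres(c("chimpanzee", "bonobo")), ape6)
  expect_equal(pan$changes, 1)
  expect_equal(pan$branch, "pan_ancestor")
  expect_false(pan$recurrent)

  afr <- fitch_assign(pres(c("chimpanzee", "bonobo", "gorilla")), ape6)
  expect_equal(afr$branch, "african_ape_ancestor")
})

test_that("discordant characters are flagged recurrent", {
  cg <- fitch_assign(pres(c("chimpanzee", "gorilla")), ape6)
  expect_gte(cg$changes, 2)
  expect_true(cg$recurrent)
  expect_true(is.na(cg$branch))

  expect_error(fitch_assign(stats::setNames(rep(NA, 6), leaves), ape6),
               "fewer than two")
})

test_that("change counts equal the brute-force minimum on all 64 characters", {
  for (mask in 0:63) {
    present <- leaves[bitwAnd(bitwShiftR(mask, 0:5), 1) == 1]
    p <- pres(present)
    got <- fitch_assign(p, ape6)$changes
    expect_equal(got, fitch_oracle(p, ape6),
                 info = paste("character:", paste(present, collapse = "+")))
  }
})

test_that("heterozygous species are missing unless opted in", {
  g <- c(chimpanzee_h1 = "inv", chimpanzee_h2 = "inv",
         bonobo_h1 = "inv", bonobo_h2 = "ref",
         gorilla_h1 = "ref", gorilla_h2 = "ref")
  p <- presence_from_genotypes(g, c("chimpanzee", "bonobo", "gorilla"))
  expect_true(p[["chimpanzee"]])
  expect_true(is.na(p[["bonobo"]]))
  expect_false(p[["gorilla"]])
  p2 <- presence_from_genotypes(g, c("chimpanzee", "bonobo", "gorilla"),
                                include_heterozygous = TRUE)
  expect_true(p2[["bonobo"]])
})

test_that("branch recovery is complete without recurrence, partial with", {
  cfg <- sim_config(inversion = list(rate_per_ma = 3, recurrent_fraction = 0))
  inv <- simulate_inversions_on_tree(ape6, cfg, seed = 3)
  asg <- assign_inversions(inv$genotypes, ape6)
  expect_gt(nrow(asg), 100)
  expect_equal(mean(asg$branch == inv$truth$branch), 1)

  cfg_r <- sim_config(inversion = list(rate_per_ma = 3,
                                       recurrent_fraction = 0.3))
  inv_r <- simulate_inversions_on_tree(ape6, cfg_r, seed = 8)
  asg_r <- assign_inversions(inv_r$genotypes, ape6)
  frac_assigned <- mean(!asg_r$recurrent)
  r <- mean(inv_r$truth$recurrent)
  expect_lt(abs(frac_assigned - (1 - r)), 0.05)
  expect_true(all(asg_r$recurrent == inv_r$truth$recurrent))
})

test_that("per-branch counts regress on branch length", {
  expect_equal(branch_count_regression(2 * (1:5), 1:5)$r_squared, 1)
  expect_equal(branch_count_regression(rep(3, 5), 1:5)$r_squared, 0)
  expect_error(branch_count_regression(1:3, rep(2, 3)), "degenerate")

  cfg <- sim_config(inversion = list(rate_per_ma = 7, recurrent_fraction = 0))
  inv <- simulate_inversions_on_tree(ape6, cfg, seed = 9)
  expect_gt(nrow(inv$genotypes), 300)
  branches <- heterokit:::node_names(ape6)[ape6$edge[, 2]]
  counts <- vapply(branches, function(b) sum(inv$truth$branch == b),
                   numeric(1))
  fit <- branch_count_regression(counts, ape6$edge.length)
  expect_gt(fit$r_squared, 0.8)
})

test_that("recall against a previous callset uses reciprocal overlap", {
  cur <- data.frame(chrom = "c1", start = (0:99) * 1e4, end = (0:99) * 1e4 + 5e3)
  expect_equal(recall_vs_previous(cur, cur)$percent_confirmed, 100)
  far <- cur; far$start <- far$start + 6e3; far$end <- far$end + 6e3
  expect_equal(recall_vs_previous(cur, far)$percent_confirmed, 0)
  expect_error(recall_vs_previous(cur, cur[0, ]), "empty previous")

  # shift invariance when both lists move together
  r1 <- recall_vs_previous(cur, far)
  cur2 <- cur; cur2$start <- cur2$start + 777; cur2$end <- cur2$end + 777
  far2 <- far; far2$start <- far2$start + 777; far2$end <- far2$end + 777
  expect_equal(recall_vs_previous(cur2, far2)$percent_confirmed,
               r1$percent_confirmed)
})

test_that("breakpoint enrichment behaves at the trivial extremes", {
  L <- c(c1 = 1e6)
  inv <- data.frame(chrom = "c1", start = c(1e5, 3e5), end = c(1.2e5, 3.3e5))
  all_cover <- data.frame(chrom = "c1", start = 0, end = 1e6)
  e <- breakpoint_feature_enrichment(inv, all_cover, L, n_perm = 100,
                                     seed = 1, pad_bp = 0)
  expect_equal(e$fold, 1)
  expect_equal(e$p_value, 1)

  expect_warning(
    e0 <- breakpoint_feature_enrichment(inv, NULL, L, n_perm = 100, seed = 1),
    "empty feature")
  expect_true(is.na(e0$fold))
  expect_equal(e0$p_value, 1)
})

test_that("enrichment is detected against a sparse feature set", {
  L <- c(c1 = 10e6)
  feat <- data.frame(chrom = "c1", start = seq(0, 9.9e6, by = 1e5))
  feat$end <- feat$start + 1e4
  set.seed(99)
  fs <- sample(feat$start, 50, replace = TRUE)
  inv <- data.frame(chrom = "c1", start = fs + 100, end = fs + 5100)
  e <- breakpoint_feature_enrichment(inv, feat, L, n_perm = 1000, seed = 42,
                                     pad_bp = 0)
  expect_equal(e$observed, 50)
  expect_gte(e$fold, 4)
  expect_lte(e$fold, 7)
  expect_lte(e$p_value, 0.001)
  expect_gte(e$p_value, 1 / 1001)
})

test_that("the null excludes placements overlapping assembly gaps", {
  L <- c(c1 = 1e6)
  # features exactly cover the gap region: excluded nulls should never hit
  gaps <- data.frame(chrom = "c1", start = 4e5, end = 6e5)
  inv <- data.frame(chrom = "c1", start = 1e5, end = 1.1e5)
  e <- breakpoint_feature_enrichment(inv, gaps, L, gaps = gaps,
                                     n_perm = 200, seed = 7, pad_bp = 0)
  expect_equal(e$null_mean, 0)
})
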