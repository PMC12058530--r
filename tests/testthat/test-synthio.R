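test_that("an empty configuration yields empty sequences and truth", {
  sim <- generate_assembly(sim_config(n_chromosomes = 0), seed = 1)
  expect_length(sim$sequences, 0)
  expect_equal(nrow(sim$truth$chromosomes), 0)
  expect_equal(nrow(sim$truth$telomeres), 0)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  p1 <- write_assembly(generate_assembly(cfg, seed = 1), d1)
  p2 <- write_assembly(generate_assembly(cfg, seed = 1), d2)
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # and a different seed changes the sequence
  s3 <- generate_assembly(cfg, seed = 2)
  s1 <- generate_assembly(cfg, seed = 1)
  expect_false(as.character(s1$sequences[[1]]) ==
                 as.character(s3$sequences[[1]]))
})

test_that("placed telomeres are recovered exactly on all 10 chromosomes", {
  sim <- generate_assembly(tiny_config(n_chromosomes = 5), seed = 1)
  expect_equal(length(sim$sequences), 10)
  n_found <- 0
  for (nm in names(sim$sequences)) {
    det <- detect_telomeres(as.character(sim$sequences[[nm]]))
    truth <- sim$truth$telomeres[sim$truth$telomeres$chrom == nm, ]
    for (term in c("p", "q")) {
      d <- det[det$terminus == term, ]
      tr <- truth[truth$terminus == term, ]
      if (nrow(d) == 1 && d$start == tr$start && d$end == tr$end) {
        n_found <- n_found + 1
      }
    }
  }
  expect_equal(n_found, 20)
})

test_that("truth intervals are contained in their chromosome and touch ends", {
  sim <- small_sim()
  lens <- chrom_lengths(sim)
  for (tab in c("telomeres", "gaps", "satellites", "arrays", "spacers",
                "cdrs")) {
    tt <- sim$truth[[tab]]
    if (!nrow(tt)) next
    expect_true(all(tt$start >= 0), info = tab)
    expect_true(all(tt$end <= lens[tt$chrom]), info = tab)
    expect_true(all(tt$start < tt$end), info = tab)
  }
  tel <- sim$truth$telomeres
  expect_true(all(tel$start == 0 | tel$end == lens[tel$chrom]))
  # truth arrays are pairwise non-overlapping per chromosome
  arr <- sim$truth$arrays
  by_chrom <- split(arr, arr$chrom)
  for (a in by_chrom) {
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
})

test_that("a chromosome too short for its features fails with the deficit", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6)
  expect_error(generate_assembly(cfg, seed = 1), "too short.*deficit")
})

test_that("configured gaps are placed and recorded", {
  cfg <- tiny_config(gaps = list(n = 1L, length_bp = 5000))
  sim <- generate_assembly(cfg, seed = 3)
  expect_equal(nrow(sim$truth$gaps), 2) # one per haplotype chromosome
  g <- sim$truth$gaps[1, ]
  s <- substr(as.character(sim$sequences[[g$chrom]]), g$start + 1, g$end)
  expect_equal(s, strrep("N", 5000))
  found <- find_gaps(as.character(sim$sequences[[g$chrom]]))
  expect_equal(found$start, g$start)
  expect_equal(found$end, g$end)
})

test_that("methylation track is hypomethylated inside truth CDRs", {
  sim <- small_sim()
  meth <- small_meth()
  cdr <- sim$truth$cdrs[1, ]
  on_chrom <- meth[meth$chrom == cdr$chrom, ]
  inside <- on_chrom$start >= cdr$start & on_chrom$start < cdr$end
  # restrict "outside" to the parent array to avoid spacer pockets
  arr <- sim$truth$arrays[sim$truth$arrays$array_id == cdr$array_id, ]
  in_array <- on_chrom$start >= arr$start & on_chrom$start < arr$end
  m_in <- mean(on_chrom$fraction[inside])
  m_out <- mean(on_chrom$fraction[in_array & !inside])
  expect_lt(m_in, m_out)
  expect_equal(m_out - m_in, 0.8, tolerance = 0.02)
  # every CpG record sits on a CG dinucleotide
  idx <- sample(nrow(on_chrom), 50)
  seqs <- substring(as.character(sim$sequences[[cdr$chrom]]),
                    on_chrom$start[idx] + 1, on_chrom$start[idx] + 2)
  expect_true(all(seqs == "CG"))
})

test_that("flat methylation config produces no callable dips", {
  cfg <- tiny_config(methylation = list(cdr_mean = 0.9, pocket_mean = 0.9,
                                        background_mean = 0.9,
                                        background_sd = 0.02))
  sim <- generate_assembly(cfg, seed = 4)
  meth <- generate_methylation(sim, seed = 4)
  arr <- sim$truth$arrays[1, ]
  expect_equal(nrow(call_cdrs(meth, arr)), 0)
})

test_that("truth CDR lengths recover the generating slope by regression", {
  cfg <- sim_config(seed = 7)
  hor <- sample_hor_lengths(cfg, 40, seed = 7)
  cdr <- sample_cdr_lengths(hor$length_bp, cfg, seed = 7)
  fit <- cdr_length_vs_array_regression(
    data.frame(array_length_bp = hor$length_bp, cdr_length_bp = cdr))
  expect_gt(fit$slope, 0.2)
  expect_lt(fit$slope, 0.4)
})

test_that("inversion simulation honours rate, placement and recurrence", {
  tree <- ape_species_tree()
  cfg0 <- sim_config(inversion = list(rate_per_ma = 0))
  expect_equal(nrow(simulate_inversions_on_tree(tree, cfg0, seed = 1)$genotypes),
               0)
  cfg <- sim_config(inversion = list(rate_per_ma = 1.5,
                                     recurrent_fraction = 0))
  inv <- simulate_inversions_on_tree(tree, cfg, seed = 3)
  expect_gt(nrow(inv$genotypes), 20)
  expect_false(any(inv$truth$recurrent))
  # each event's inverted leaves are exactly the clade of its truth branch
  for (i in seq_len(min(nrow(inv$genotypes), 50))) {
    leaves <- tree$tip.label
    present <- leaves[unlist(inv$genotypes[i, leaves]) == "inv"]
    br <- inv$truth$branch[i]
    node <- match(br, c(tree$tip.label, tree$node.label))
    expect_setequal(present, heterokit:::clade_tips(tree, node))
  }
  # a tree without branch lengths is rejected
  t0 <- tree; t0$edge.length <- NULL
  expect_error(simulate_inversions_on_tree(t0, cfg, seed = 1), "zero-length")
})
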