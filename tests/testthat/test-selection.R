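test_that("the scenario grid has the designed structure", {
  g1 <- build_parameter_grid(1)
  expect_equal(nrow(g1), 100)
  g4 <- build_parameter_grid(c(1, 3, 5, 10))
  expect_equal(nrow(g4), 400)
  expect_false(any(g4$h == 0))
  expect_false(any(g4$A %in% c(0, 1)))
  gx <- build_parameter_grid(1, sex_linked = TRUE)
  expect_equal(nrow(gx), 100)
  expect_true(all(gx$sex_linked))
  expect_error(build_parameter_grid(3, sex_linked = TRUE), "n_loci = 1")
  expect_error(build_parameter_grid(1, h = c(0, 0.5)), "excluded")
})

test_that("parent selection applies the truncation criteria with fallback", {
  arch <- genetic_architecture(1, h = 0, baseline = 0.5)
  coh <- found_cohort(arch, 100)
  assay <- run_dispersal_assay(coh, k = 3)

  # 45 qualifiers -> exactly 30 sampled
  assay$counts <- rep(0L, 100)
  assay$counts[1:45] <- 3L
  set.seed(31)
  sel <- select_parents(assay, "high", n_par = 30)
  expect_equal(length(sel$mothers$male) + length(sel$fathers$male), 30)
  expect_true(all(!sel$mothers$male) && all(sel$fathers$male))

  # 12 qualifiers -> all taken
  assay$counts <- rep(1L, 100)
  assay$counts[5:16] <- 0L
  sel <- select_parents(assay, "low", n_par = 30)
  expect_equal(length(sel$mothers$male) + length(sel$fathers$male), 12)

  # qualifiers all one sex -> closest individual of the other sex is added
  assay$counts <- rep(0L, 100)
  assay$counts[assay$male] <- 3L           # only males qualify for "high"
  assay$counts[which(!assay$male)[1]] <- 2L  # the closest female
  sel <- select_parents(assay, "high", n_par = 30)
  expect_equal(length(sel$mothers$male), 1)     # exactly one female backfilled
  expect_equal(length(sel$fathers$male), 30)    # the male qualifiers
})

test_that("selection drives allele frequency in the selected direction", {
  arch <- genetic_architecture(1, d = 0.5, h = 1, A = 0.5)
  up <- vapply(1:50, function(r) {
    tr <- run_selection_replicate(arch, "high", seed = 1000 + r)
    tr$allele_freq[5] > tr$allele_freq[1]
  }, TRUE)
  expect_gte(mean(up), 0.95)

  # low regime declines towards the floor
  archl <- genetic_architecture(1, d = 0.5, h = 0.6, A = 0.8)
  tr <- run_selection_replicate(archl, "low", seed = 77)
  expect_lt(tr$mean_dispersals[5], tr$mean_dispersals[1])
  expect_lt(tr$allele_freq[5], tr$allele_freq[1])

  # no variance, no response: fixed founders give a flat trajectory at 3s
  archf <- genetic_architecture(1, d = 0.5, h = 1, A = 1)
  trf <- run_selection_replicate(archf, "high", seed = 5)
  expect_true(all(trf$allele_freq == 1))
  expect_true(all(trf$mean_dispersals == 3))
})

test_that("high and low regimes are indistinguishable when h = 0", {
  arch <- genetic_architecture(1, d = 0.5, h = 0, A = 0.5)
  g5 <- function(regime, seeds) vapply(seeds, function(s)
    run_selection_replicate(arch, regime, seed = s)$mean_dispersals[5], 0)
  hi <- g5("high", 1:100)
  lo <- g5("low", 201:300)
  expect_gt(t.test(hi, lo)$p.value, 0.01)
})

test_that("generation-1 behaviour depends only on the expected score", {
  # equal E[s]: 1 locus at A=0.5,d=0.5 vs 10 loci at A=0.5,d=0.5 both give
  # E[s]=0.5 -> equal founding means
  m1 <- vapply(1:30, function(r) run_selection_replicate(
    genetic_architecture(1, d = 0.5, h = 0.6, A = 0.5),
    "high", seed = 400 + r)$mean_dispersals[1], 0)
  m10 <- vapply(1:30, function(r) run_selection_replicate(
    genetic_architecture(10, d = 0.5, h = 0.6, A = 0.5),
    "high", seed = 500 + r)$mean_dispersals[1], 0)
  expect_gt(t.test(m1, m10)$p.value, 0.01)
})

test_that("the parameter scan is reproducible and correctly shaped", {
  grid <- build_parameter_grid(1)[c(1, 50, 100), ]
  s1 <- run_parameter_scan(grid, n_repeats = 4, seed = 9)
  s2 <- run_parameter_scan(grid, n_repeats = 4, seed = 9)
  expect_identical(s1, s2)
  s3 <- run_parameter_scan(grid, n_repeats = 4, seed = 10)
  expect_false(identical(s1$mean_dispersals, s3$mean_dispersals))

  # rows: scenarios x repeats x regimes x generations
  expect_equal(nrow(s1), 3 * 4 * 2 * 5)
  expect_setequal(unique(s1$regime), c("high", "low"))
  expect_true(all(s1$allele_freq >= 0 & s1$allele_freq <= 1))

  # a replicate regenerates in isolation from its derived substream
  i <- 2; r <- 3
  arch <- genetic_architecture(grid$n_loci[i], grid$sex_linked[i],
                               grid$d[i], grid$h[i], grid$A[i])
  solo <- run_selection_replicate(arch, "high",
                                  seed = dispersim:::derive_seed(9, i, r, 1))
  sub <- s1[s1$scenario == i & s1$replicate == r & s1$regime == "high", ]
  expect_equal(sub$mean_dispersals, solo$mean_dispersals)
  expect_equal(sub$allele_freq, solo$allele_freq)
})
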