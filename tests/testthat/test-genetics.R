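test_that("architecture construction validates its parameters", {
  arch <- genetic_architecture(3, FALSE, d = 0.25, h = 0.8, A = 0.4)
  expect_s3_class(arch, "genetic_architecture")
  expect_identical(arch$n_loci, 3L)
  expect_error(genetic_architecture(2, sex_linked = TRUE), "single locus")
  expect_error(genetic_architecture(0), "positive")
  expect_error(genetic_architecture(d = 1.2), "\\[0, 1\\]")
  expect_error(genetic_architecture(h = -0.1), "\\[0, 1\\]")
  expect_error(genetic_architecture(A = 2), "\\[0, 1\\]")
  expect_output(print(arch), "3 autosomal")
})

test_that("genotypic scores follow the per-locus 0/d/1 rule", {
  # homozygous dispersal individuals score 1 whatever the dominance
  for (d in c(0, 0.3, 1)) {
    arch <- genetic_architecture(2, d = d)
    coh <- fixed_cohort(arch, rbind(c(2, 2)), male = FALSE)
    expect_equal(genotypic_score(coh), 1)
  }
  # single-locus heterozygote scores d
  arch1 <- genetic_architecture(1, d = 0.5)
  het <- fixed_cohort(arch1, rbind(1), male = FALSE)
  expect_equal(genotypic_score(het), 0.5)
  # three loci (hom-disp, het, hom-non) with d = 1 -> mean(1, 1, 0) = 2/3
  arch3 <- genetic_architecture(3, d = 1)
  mix <- fixed_cohort(arch3, rbind(c(2, 1, 0)), male = FALSE)
  expect_equal(genotypic_score(mix), 2 / 3)
  # X-linked male scores exactly his single allele
  archx <- genetic_architecture(1, sex_linked = TRUE, d = 0.5)
  xm <- fixed_cohort(archx, rbind(1, 0), male = c(TRUE, TRUE))
  expect_equal(genotypic_score(xm), c(1, 0))
})

test_that("dispersal probability is the h-weighted mix of score and baseline", {
  arch <- genetic_architecture(1, d = 0.5, h = 1, A = 0.5)
  hom <- fixed_cohort(arch, rbind(2), male = FALSE)
  expect_equal(dispersal_probability(hom), 1)      # s = 1, h = 1
  arch0 <- genetic_architecture(1, d = 0.5, h = 0, A = 0.5, baseline = 0.5)
  expect_equal(dispersal_probability(fixed_cohort(arch0, rbind(0), FALSE)), 0.5)
  expect_equal(dispersal_probability(fixed_cohort(arch0, rbind(2), FALSE)), 0.5)
  # heterozygote, d = 0.5, h = 0.6, b = 0.5: 0.6*0.5 + 0.4*0.5 = 0.5
  arch6 <- genetic_architecture(1, d = 0.5, h = 0.6)
  expect_equal(dispersal_probability(fixed_cohort(arch6, rbind(1), FALSE)), 0.5)
  # affine in s: p collapses to baseline at h = 0 and is monotone in s
  archm <- genetic_architecture(1, d = 0.4, h = 0.7, baseline = 0.2)
  p <- dispersal_probability(fixed_cohort(archm, rbind(0, 1, 2), rep(FALSE, 3)))
  expect_equal(p, 0.7 * c(0, 0.4, 1) + 0.3 * 0.2)
  expect_true(all(diff(p) > 0))
})

test_that("founding draws alleles at frequency A and splits sexes evenly", {
  arch1 <- genetic_architecture(2, A = 1)
  coh <- found_cohort(arch1, n = 50)
  expect_equal(allele_freq(coh), 1)
  expect_true(all(genotypic_score(coh) == 1))

  set.seed(101)
  arch <- genetic_architecture(1, A = 0.8)
  coh <- found_cohort(arch, n = 200)
  se <- sqrt(0.8 * 0.2 / 400)
  expect_lt(abs(allele_freq(coh) - 0.8), 3 * se)
  expect_equal(sum(coh$male), 100)                 # deterministic 1:1 split
  expect_equal(sum(!coh$male), 100)

  expect_error(found_cohort(arch, n = 0), "positive")
  expect_error(found_cohort(arch, sex_ratio = 1.5), "sex_ratio")
})

test_that("gametes segregate independently at one half per allele", {
  set.seed(7)
  arch <- genetic_architecture(1, d = 0.5)
  het <- fixed_cohort(arch, matrix(1, nrow = 10000), rep(FALSE, 10000))
  g <- make_gametes(het)
  # transmission frequency of the dispersal allele: 0.5 within binomial error
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(g) - 0.5), 4 * se)

  hom <- fixed_cohort(arch, matrix(2, nrow = 20), rep(FALSE, 20))
  expect_true(all(make_gametes(hom) == 1))         # homozygote gametes fixed
})

test_that("X-linked fathers transmit their X to all daughters and no sons", {
  archx <- genetic_architecture(1, sex_linked = TRUE, d = 0.5, A = 0.5)
  father <- fixed_cohort(archx, rbind(1), male = TRUE)      # carries X^disp
  mother <- fixed_cohort(archx, rbind(0), male = FALSE)     # no dispersal allele
  set.seed(3)
  off <- breed_cohort(mother, father, n_offspring = 400)
  dgt <- !off$male
  expect_true(all(off$paternal[dgt, 1] == 1))      # every daughter has it
  expect_true(all(is.na(off$paternal[off$male, 1])))  # sons carry the Y
  expect_true(all(off$maternal[, 1] == 0))         # mother contributes 0
  # daughters are heterozygous, sons hemizygous null
  expect_equal(unname(genotypic_score(off)[dgt][1]), 0.5)
  expect_true(all(genotypic_score(off)[off$male] == 0))
})

test_that("breeding preserves allele frequency under random mating", {
  arch <- genetic_architecture(1, d = 0.5, A = 0.5)
  # homozygous crosses are deterministic
  hi <- found_cohort(genetic_architecture(1, A = 1), n = 20)
  lo <- found_cohort(genetic_architecture(1, A = 0), n = 20)
  hh <- breed_cohort(hi[!hi$male], hi[hi$male], 50)
  expect_equal(allele_freq(hh), 1)
  hl <- breed_cohort(lo[!lo$male], hi[hi$male], 50)
  expect_true(all(hl$maternal == 0) && all(hl$paternal == 1))  # all heterozygous
  expect_true(all(genotypic_score(hl) == 0.5))

  # conservation: offspring frequency equals parental transmission frequency
  set.seed(11)
  coh <- found_cohort(arch, n = 200)
  parent_freq <- allele_freq(coh)
  off <- breed_cohort(coh[!coh$male], coh[coh$male], n_offspring = 10000)
  se <- sqrt(parent_freq * (1 - parent_freq) / (2 * 10000))
  expect_lt(abs(allele_freq(off) - parent_freq), 4 * se)

  expect_error(breed_cohort(coh[coh$male], coh[coh$male], 10), "all-female")
  expect_error(breed_cohort(coh[!coh$male], coh[integer(0)], 10), "all-male")
})

test_that("cohorts serialise to a tidy per-individual table", {
  set.seed(2)
  coh <- found_cohort(genetic_architecture(3, A = 0.5), n = 10,
                      line_id = "L7", generation = 2)
  df <- as.data.frame(coh)
  expect_equal(nrow(df), 10)
  expect_named(df, c("line_id", "generation", "sex", "locus1", "locus2",
                     "locus3"))
  expect_true(all(df$locus1 %in% 0:2))
  expect_equal(df$generation, rep(2L, 10))
})
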