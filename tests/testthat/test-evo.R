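test_that("phenotype sums the shared locus, the own-sex locus and noise", {
  pop <- list(
    alleles = matrix(c(1, 1, 0.5, 0.5, 9, 9,   # male: female locus silent
                       0, 0, 9, 9, 1, 2),      # female: male locus silent
                     nrow = 2, byrow = TRUE,
                     dimnames = list(NULL, c("shared.1", "shared.2",
                                             "male.1", "male.2",
                                             "female.1", "female.2"))),
    sex = c(TRUE, FALSE), E = c(0, 0))
  expect_equal(evoPhenotype(pop), c(3, 3))
  # allele order within a locus is irrelevant
  pop2 <- pop
  pop2$alleles[, c("shared.1", "shared.2")] <-
    pop$alleles[, c("shared.2", "shared.1")]
  expect_equal(evoPhenotype(pop2), evoPhenotype(pop))
})

test_that("Gaussian fitness matches closed forms", {
  expect_equal(evoFitness(0.05, 0), 1)
  expect_equal(evoFitness(0, 137), 1)
  expect_equal(evoFitness(0.05, 2), exp(-0.2))
  expect_error(evoFitness(-1, 0))
})

test_that("mutation respects its rate and leaves rate-zero populations alone", {
  set.seed(1)
  pop <- list(alleles = matrix(0, 2000, 6,
                               dimnames = list(NULL, c("shared.1",
                                 "shared.2", "male.1", "male.2",
                                 "female.1", "female.2"))),
              sex = rep(c(TRUE, FALSE), 1000), E = rnorm(2000))
  expect_identical(evoMutate(pop, 0), pop)
  mut <- evoMutate(pop, 5e-3)
  nHits <- sum(mut$alleles != 0)
  # 3 loci x 2000 individuals x 5e-3 = 30 expected
  expect_gt(nHits, 10); expect_lt(nHits, 60)
  # at most one allele per individual-locus pair changes
  for (locus in c("shared", "male", "female")) {
    both <- rowSums(mut$alleles[, paste0(locus, c(".1", ".2"))] != 0)
    expect_true(all(both <= 1))
  }
})

test_that("census size is conserved and runs are reproducible", {
  par <- evoParams(popSize = 100L, nParentPairs = 20L,
                   offspringPerPair = 5L, nGenerations = 30L,
                   recordEvery = 10L, nReplicates = 2L, seed = 5)
  tr <- runEvoSim(par)
  expect_identical(tr, runEvoSim(par))
  expect_setequal(unique(tr$generation), c(10, 20, 30))
  expect_true(all(tr$var_pheno_male >= 0 & tr$var_shared_locus >= 0))
})

test_that("neutral drift shrinks shared-locus variance without mutation", {
  par <- evoParams(popSize = 100L, sMale = 0, sFemale = 0, mutRate = 0,
                   nParentPairs = 20L, offspringPerPair = 5L,
                   nGenerations = 200L, recordEvery = 20L,
                   nReplicates = 8L, seed = 7)
  tr <- runEvoSim(par)
  mv <- tapply(tr$var_shared_locus, tr$generation, mean)
  # geometric decay by drift: the late mean variance is well below the
  # early one (variance can hit 0 by fixation, so no log regression)
  expect_lt(mv[length(mv)], 0.5 * mv[1])
})
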