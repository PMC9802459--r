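test_that("hypergeometric upper tail matches combinatorial enumeration", {
  expect_equal(hypergeomTest(0, 5, 5, 20), 1)
  # universe 10, 5 labeled, set of 5, full overlap: 1 / C(10,5)
  expect_equal(hypergeomTest(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:15) {
    u <- sample(6:12, 1)
    lab <- sample(1:(u - 1), 1)
    k <- sample(1:(u - 1), 1)
    ov <- sample(0:min(lab, k), 1)
    expect_equal(hypergeomTest(ov, k, lab, u),
                 hypergeomOracle(ov, k, lab, u), tolerance = 1e-10)
  }
  expect_error(hypergeomTest(6, 5, 5, 10), "inconsistent")
})

## shared fixture: labeled universes for a few synthetic tissues
makeLabelTables <- function(nTissues = 4, nGenes = 400, nLabeled = 40,
                            seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(nGenes))
  lab <- lapply(seq_len(nTissues), function(t) {
    l <- rep("not_sdv", nGenes)
    l[sample.int(nGenes, nLabeled)] <- "male_higher"
    setNames(l, genes)
  })
  names(lab) <- paste0("tissue", seq_len(nTissues))
  lab
}

test_that("combined statistic is zero and insignificant when nothing overlaps", {
  labs <- makeLabelTables()
  universe <- names(labs[[1]])
  # sets disjoint from every labeled gene in every tissue are impossible
  # to construct in general; instead use sets equal to the whole universe:
  # overlap is forced, p = 1 in every tissue, T = 0
  sets <- list(everything = universe)
  mr <- fisherCombinedPerm(labs, sets, "male_higher", B = 200, seed = 2)
  expect_equal(mr$T_obs, 0, tolerance = 1e-10)
  expect_gt(mr$perm_p, 0.9)
})

test_that("planted enrichment is detected and null sets stay null", {
  set.seed(7)
  nGenes <- 400
  genes <- sprintf("g%04d", seq_len(nGenes))
  labeledIdx <- 1:40
  labs <- lapply(1:4, function(t) {
    l <- rep("not_sdv", nGenes)
    l[labeledIdx] <- "male_higher"
    setNames(l, genes)
  })
  names(labs) <- paste0("tissue", 1:4)
  sets <- simulateGeneSets(12, genes,
                           setNames(labs[[1]], genes), "male_higher",
                           plantedOverlap = 0.8, nPlanted = 4,
                           setSizeRange = c(25, 40), seed = 3)
  mr <- fisherCombinedPerm(labs, sets, "male_higher", B = 500, seed = 5)
  planted <- attr(sets, "planted")
  expect_true(all(mr$q[planted] < 0.05))
  # null sets stay mostly null (a single dip below alpha among 8 null
  # sets is within expectation)
  expect_lte(sum(mr$perm_p[!planted] < 0.05), 1)
})

test_that("tissue order does not change the combined statistic", {
  labs <- makeLabelTables(seed = 9)
  sets <- list(s1 = names(labs[[1]])[1:60], s2 = names(labs[[1]])[51:140])
  a <- fisherCombinedPerm(labs, sets, "male_higher", B = 100, seed = 1)
  b <- fisherCombinedPerm(rev(labs), sets, "male_higher", B = 100,
                          seed = 1)
  expect_equal(a$T_obs, b$T_obs, tolerance = 1e-10)
})

test_that("tissues below the inclusion threshold are excluded", {
  labs <- makeLabelTables(nTissues = 2, nLabeled = 40, seed = 2)
  labs$sparse <- setNames(rep("not_sdv", 400), names(labs[[1]]))
  labs$sparse[1:5] <- "male_higher"  # < 20 labeled genes
  sets <- list(s = names(labs[[1]])[1:50])
  expect_warning(
    mr <- fisherCombinedPerm(labs, sets, "male_higher", B = 50, seed = 1),
    "coarse")
  expect_false("sparse" %in% S4Vectors::metadata(mr)$tissues_used)
})

test_that("balanced 2x2 tables give unit odds ratio and fold", {
  genes <- sprintf("g%02d", 1:40)
  sdv <- setNames(rep(c(TRUE, FALSE), each = 20), genes)
  eg <- setNames(rep(c(TRUE, FALSE), 20), genes)
  # overlap 10, expected 20*20/40 = 10 -> fold 1, Fisher p = 1
  res <- eGeneDepletion(list(t = sdv), list(t = eg), B = 50, seed = 1)
  expect_equal(res$per_tissue$fold, 1)
  expect_equal(res$per_tissue$fisher_p, 1)
  expect_equal(res$median_fold, 1)
})

test_that("planted depletion across tissues yields a low median fold", {
  set.seed(11)
  genes <- sprintf("g%04d", 1:800)
  sdvFlags <- lapply(1:20, function(t)
    setNames(seq_along(genes) %in% sample.int(800, 80), genes))
  names(sdvFlags) <- paste0("t", 1:20)
  egFlags <- simulateEGeneLabels(sdvFlags, depletionFactor = 0.5,
                                 baseRate = 0.4, seed = 12)
  res <- eGeneDepletion(sdvFlags, egFlags, B = 500, seed = 13)
  expect_lt(res$median_fold, 1)
  expect_lt(res$perm_p, 0.05)
  # and with no planted association the test is well behaved
  egNull <- simulateEGeneLabels(sdvFlags, depletionFactor = 1,
                                baseRate = 0.4, seed = 14)
  resNull <- eGeneDepletion(sdvFlags, egNull, B = 300, seed = 15)
  expect_gt(resNull$perm_p, 0.05)
})

test_that("rank test is two-sided, sensitive, and rank-invariant", {
  expect_gt(scoreRankTest(1:20, 1:20), 0.99)
  set.seed(3)
  a <- rnorm(200); b <- rnorm(200) + 3
  expect_lt(scoreRankTest(a, b), 1e-6)
  # invariance to a strictly monotone transform of the pooled scores
  expect_equal(scoreRankTest(a, b), scoreRankTest(exp(a), exp(b)),
               tolerance = 1e-12)
  expect_error(scoreRankTest(numeric(0), b), "empty")
})
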