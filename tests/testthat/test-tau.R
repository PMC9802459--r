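test_that("tau hits its closed-form worked values", {
  expect_equal(tauIndex(c(1, 0, 0)), 1)
  expect_equal(tauIndex(c(3, 3, 3)), 0)
  expect_equal(tauIndex(c(1, 0.5, 0)), 0.75)
  expect_true(is.na(tauIndex(c(0, 0, 0))))
  expect_error(tauIndex(c(-1, 2, 0)), "nonnegative")
})

test_that("tau is scale-invariant and monotone in the dominant context", {
  set.seed(1)
  for (i in 1:20) {
    x <- runif(4)
    expect_equal(tauIndex(x), tauIndex(7.3 * x), tolerance = 1e-12)
  }
  x <- c(2, 1, 0.5)
  expect_gte(tauIndex(c(4, 1, 0.5)), tauIndex(x))
})

test_that("pseudo-bulk aggregation is additive and order-invariant", {
  sc <- simulateSCCounts(nCellsPerType = c(8, 6, 5), seed = 2)
  pb <- pseudoBulk(sc$counts, sc$cellType)
  # each pseudo-bulk CPM column sums to one million
  expect_equal(unname(colSums(pb$cpm)), rep(1e6, 3), tolerance = 1e-6)
  # merging cells of a type = summing their count vectors
  manual <- sapply(levels(sc$cellType), function(tp)
    rowSums(sc$counts[, sc$cellType == tp, drop = FALSE]))
  expect_equal(unname(pb$counts), unname(manual))
  # permuting cells changes nothing
  set.seed(3); idx <- sample(ncol(sc$counts))
  pb2 <- pseudoBulk(sc$counts[, idx], sc$cellType[idx])
  expect_equal(pb$counts, pb2$counts)
  expect_error(pseudoBulk(sc$counts, sc$cellType[-1]), "label per cell")
  labNA <- sc$cellType; labNA[1] <- NA
  expect_error(pseudoBulk(sc$counts, labNA), "unlabeled")
})

test_that("marker genes score tau = 1 and housekeeping genes near 0", {
  sc <- simulateSCCounts(seed = 4)
  tau <- cellTypeTau(sc$counts, sc$cellType)
  markers <- grep("^marker", names(tau))
  hk <- grep("^hk", names(tau))
  expect_true(all(tau[markers] == 1))
  expect_lt(max(tau[hk]), 0.15)
})
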