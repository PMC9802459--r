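test_that("sample pairs have the requested negative binomial moments", {
  p <- drawNBPair(10000, 10000, mu = 1500, sigma1 = 0.1, sigma2 = 0.1,
                  seed = 1)
  for (y in p) {
    expect_equal(mean(y), 1500, tolerance = 0.02)
    expect_equal(var(y), 1500 + 0.1 * 1500^2, tolerance = 0.1)
  }
  # same seed, same draws
  expect_identical(drawNBPair(50, 50, 100, 0.2, 0.3, seed = 3),
                   drawNBPair(50, 50, 100, 0.2, 0.3, seed = 3))
})

test_that("all three tests behave sensibly on degenerate and strong inputs", {
  same <- rep(5, 40)
  p <- runThreeTests(same, same)
  expect_true(all(p == 1))
  expect_true(attr(p, "degenerate"))
  set.seed(2)
  pair <- drawNBPair(200, 200, 1500, 0.05, 0.5)
  p2 <- runThreeTests(pair$y1, pair$y2)
  expect_true(all(p2 < 0.05))
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_error(runThreeTests(numeric(0), same), "empty")
})

test_that("power rises with the dispersion difference and FPR sits near alpha", {
  spec <- powerGridSpec(groupSizes = list(c(100, 100)), sigmaBase = 0.1,
                        deltaFrac = c(0, 0.5, 2), reps = 150, seed = 5)
  tab <- powerGrid(spec)
  expect_true(all(tab$power_or_fpr >= 0 & tab$power_or_fpr <= 1))
  expect_equal(tab$mc_se,
               sqrt(tab$power_or_fpr * (1 - tab$power_or_fpr) / 150))
  for (tst in unique(tab$test)) {
    sub <- tab[tab$test == tst, ]
    sub <- sub[order(sub$delta_sigma), ]
    # nondecreasing power in delta (2 MC-SE slack)
    expect_true(all(diff(sub$power_or_fpr) >= -2 * max(sub$mc_se)))
    # null rows are FPR estimates near alpha (loose at 150 reps;
    # Fligner-Killeen is allowed to be conservative)
    expect_lt(sub$power_or_fpr[sub$delta_sigma == 0], 0.12)
  }
})
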