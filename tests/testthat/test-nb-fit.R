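test_that("log-likelihood matches closed forms and the Poisson limit", {
  # y = 0, mu = 1500, sigma = 0.1: (1/sigma) * log(1/(1 + sigma*mu))
  expect_equal(nbLogLik(0, 1500, 0.1), 10 * log(1 / 151), tolerance = 1e-10)
  # Poisson limit: log P(0 | mu = 1) = -1
  expect_equal(nbLogLik(0, 1, 1e-12), -1, tolerance = 1e-6)
  # agreement with dnbinom in the regular regime
  y <- c(0, 3, 17, 250)
  expect_equal(nbLogLik(y, 40, 0.25),
               sum(dnbinom(y, mu = 40, size = 4, log = TRUE)),
               tolerance = 1e-10)
  expect_error(nbLogLik(-1, 5, 0.1), "nonnegative")
  expect_error(nbLogLik(3, Inf, 0.1), "finite")
})

test_that("pmf implied by the log-likelihood is normalized", {
  p <- vapply(0:10000, function(y) exp(nbLogLik(y, 5, 0.3)), 0)
  expect_equal(sum(p), 1, tolerance = 1e-8)
})

test_that("intercept-only mean fit recovers the sample mean", {
  set.seed(1)
  y <- rnbinom(500, mu = 70, size = 8)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- nbFit(y = y, Xmu = X, Xsigma = X)
  expect_true(isConverged(fit))
  expect_equal(exp(unname(betaMu(fit))), mean(y), tolerance = 1e-4)
})

test_that("coefficients are recovered within Monte Carlo error at n = 1e4", {
  set.seed(7)
  n <- 10000
  x <- rep(0:1, each = n / 2)
  X <- cbind(`(Intercept)` = 1, x = x)
  off <- rnorm(n, 0, 0.2)
  bMuTrue <- c(4, 0.5); bSigTrue <- c(-2.5, 0.8)
  mu <- exp(drop(X %*% bMuTrue) + off)
  sig <- exp(drop(X %*% bSigTrue))
  y <- rnbinom(n, mu = mu, size = 1 / sig)
  fit <- nbFit(y = y, Xmu = X, Xsigma = X, offset = off)
  expect_true(isConverged(fit))
  # asymptotic SEs are O(1/sqrt(n)); 3 MC SEs with a generous constant
  expect_equal(unname(betaMu(fit)), bMuTrue, tolerance = 0.05)
  expect_equal(unname(betaSigma(fit)), bSigTrue, tolerance = 0.15)
  # MLE beats the generating parameters on the same data
  expect_gte(logLik(fit) + 1e-6, nbLogLik(y, mu, sig))
})

test_that("lattice search never beats the fitted optimum on tiny designs", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 12
    x <- rep(0:1, each = 6)
    X <- cbind(`(Intercept)` = 1, x = x)
    y <- rnbinom(n, mu = exp(2 + 0.7 * x), size = 1 / 0.3)
    if (all(y == 0)) next
    fit <- nbFit(y = y, Xmu = X, Xsigma = X)
    best <- latticeBestLoglik(y, X)
    expect_gte(logLik(fit), best - 1e-3)
  }
})

test_that("adding c to the offset and subtracting it from the intercept is a no-op", {
  set.seed(4)
  y <- rnbinom(60, mu = 30, size = 5)
  X <- matrix(1, 60, 1)
  f1 <- nbFit(y = y, Xmu = X, Xsigma = X, offset = rep(0, 60))
  f2 <- nbFit(y = y, Xmu = X, Xsigma = X, offset = rep(1.3, 60))
  expect_equal(logLik(f1), logLik(f2), tolerance = 1e-6)
  expect_equal(unname(betaMu(f1)), unname(betaMu(f2)) + 1.3,
               tolerance = 1e-4)
})

test_that("nested models never exceed the full model's likelihood", {
  set.seed(5)
  x <- rep(0:1, each = 50)
  X <- cbind(1, x)
  X0 <- X[, 1, drop = FALSE]
  for (rep in 1:5) {
    y <- rnbinom(100, mu = 50, size = 1 / 0.2)
    full <- nbFit(y = y, Xmu = X, Xsigma = X)
    m2 <- nbFit(y = y, Xmu = X, Xsigma = X0)
    m3 <- nbFit(y = y, Xmu = X0, Xsigma = X)
    expect_gte(logLik(full) + 1e-6, logLik(m2))
    expect_gte(logLik(full) + 1e-6, logLik(m3))
  }
})

test_that("likelihood-ratio test gives textbook chi-square p-values", {
  f <- new("NBFit", betaMu = 0, betaSigma = 0, logLik = -100,
           converged = TRUE, nIter = 1L, gradNorm = 0)
  expect_equal(nbLRT(f, f), 1)
  r <- new("NBFit", betaMu = 0, betaSigma = 0, logLik = -100 - 3.841 / 2,
           converged = TRUE, nIter = 1L, gradNorm = 0)
  expect_equal(nbLRT(f, r, df = 1), 0.05, tolerance = 1e-3)
  better <- new("NBFit", betaMu = 0, betaSigma = 0, logLik = -90,
                converged = TRUE, nIter = 1L, gradNorm = 0)
  expect_error(nbLRT(f, better), "fit failure")
})

test_that("design validation rejects malformed inputs", {
  y <- rnbinom(10, mu = 5, size = 2)
  X <- cbind(1, 1:10)
  expect_error(nbDesign(y, X[1:5, ], X), "rows")
  expect_error(nbDesign(y, cbind(1:10), X), "intercept")
  expect_error(nbDesign(y, cbind(1, 1:10, 2 * (1:10)), X),
               "rank-deficient")
  expect_error(nbFit(y = rep(0, 10), Xmu = X, Xsigma = X), "all zero")
})
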