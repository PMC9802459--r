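## Shared fixtures and independent oracles. Everything is generated in
## code; moderately expensive objects are memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

## A small study with strong planted effects, used by several files.
smallStudy <- function() {
  cached("smallStudy", simulateStudy(synthConfig(
    nGenes = 80, nMale = 80, nFemale = 80, sdvFraction = 0.15,
    sdvLogSigmaEffect = 2, seed = 42)))
}

## Brute-force lattice maximizer of the NB location-scale likelihood for
## tiny designs: grid over (intercept_mu, slope_mu, intercept_s, slope_s).
latticeBestLoglik <- function(y, X, offset = rep(0, length(y)),
                              muRange = c(-2, 6), sRange = c(-6, 3),
                              steps = 25) {
  b0 <- seq(muRange[1], muRange[2], length.out = steps)
  b1 <- seq(-2, 2, length.out = steps)
  s0 <- seq(sRange[1], sRange[2], length.out = steps)
  s1 <- seq(-2, 2, length.out = steps)
  best <- -Inf
  hasSlope <- ncol(X) > 1
  for (i0 in b0) for (i1 in (if (hasSlope) b1 else 0)) {
    mu <- exp(X[, 1] * i0 + (if (hasSlope) X[, 2] * i1 else 0) + offset)
    for (j0 in s0) for (j1 in (if (hasSlope) s1 else 0)) {
      sig <- exp(X[, 1] * j0 + (if (hasSlope) X[, 2] * j1 else 0))
      ll <- nbLogLik(y, mu, sig)
      if (ll > best) best <- ll
    }
  }
  best
}

## Closed-form BH step-up (independent of stats::p.adjust).
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

## Exact upper-tail hypergeometric by enumeration over all draws
## (universe <= 12), counting draws with at least `overlap` labeled.
hypergeomOracle <- function(overlap, setSize, labelCount, universeSize) {
  draws <- combn(universeSize, setSize)
  labeled <- seq_len(labelCount)  # wlog the first labelCount ids
  hits <- apply(draws, 2, function(d) sum(d %in% labeled) >= overlap)
  mean(hits)
}
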