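## Power / false-positive-rate simulation study comparing three tests for
## a group difference in count variability: the Fligner-Killeen test and
## Levene's test on ln(counts + 1), and the NB location-scale LRT on raw
## counts (sigma ~ group, mu ~ group vs constant sigma, mu ~ group).

#' Draw a pair of NB samples with equal means
#'
#' @param n1,n2 group sizes.
#' @param mu common mean.
#' @param sigma1,sigma2 group overdispersions (\eqn{\sigma = 1/\theta}).
#' @param seed optional integer seed.
#' @return List with integer vectors `y1`, `y2`.
#' @export
drawNBPair <- function(n1, n2, mu, sigma1, sigma2, seed = NULL) {
  stopifnot(n1 > 0, n2 > 0, mu > 0, sigma1 >= 0, sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  drawOne <- function(n, s) {
    if (s < 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / s)
  }
  list(y1 = drawOne(n1, sigma1), y2 = drawOne(n2, sigma2))
}

#' Apply the three variance-difference tests to a sample pair
#'
#' Fligner-Killeen and Levene (mean-centered by default) are applied to
#' `ln(counts + 1)`; the NB location-scale LRT is applied to the raw
#' counts, comparing \eqn{\sigma \sim group, \mu \sim group} against
#' constant \eqn{\sigma}, \eqn{\mu \sim group} (1 df). A transformed
#' sample that is constant within both groups makes the rank tests
#' degenerate; their p is reported as 1 with a flag.
#'
#' @param y1,y2 raw count vectors.
#' @param leveneCenter centering for Levene's test: `"mean"` (classical)
#'   or `"median"` (Brown-Forsythe).
#' @return Named numeric: `fligner_killeen`, `levene`, `nb_lrt`, with
#'   attribute `"degenerate"` flagging rank tests on constant data.
#' @export
runThreeTests <- function(y1, y2, leveneCenter = c("mean", "median")) {
  leveneCenter <- match.arg(leveneCenter)
  if (length(y1) == 0 || length(y2) == 0) stop("empty sample")
  g <- factor(rep(c("a", "b"), c(length(y1), length(y2))))
  lny <- log(c(y1, y2) + 1)
  degenerate <- var(lny[g == "a"]) == 0 && var(lny[g == "b"]) == 0
  if (degenerate) {
    pFK <- pLev <- 1
  } else {
    pFK <- fligner.test(lny, g)$p.value
    centerFun <- if (leveneCenter == "mean") mean else median
    lev <- car::leveneTest(lny, g, center = centerFun)
    pLev <- lev[["Pr(>F)"]][1]
  }
  y <- c(y1, y2)
  X <- cbind(`(Intercept)` = 1, group = as.numeric(g == "b"))
  X0 <- X[, 1, drop = FALSE]
  full <- nbFit(y = y, Xmu = X, Xsigma = X)
  red <- nbFit(y = y, Xmu = X, Xsigma = X0)
  pNB <- if (isConverged(full) && isConverged(red))
    nbLRT(full, red, df = 1) else NA_real_
  structure(c(fligner_killeen = pFK, levene = pLev, nb_lrt = pNB),
            degenerate = degenerate)
}

#' Specification of a power/FPR simulation grid
#'
#' @param mu common NB mean (paper value 1500).
#' @param groupSizes list of `c(n1, n2)` pairs; the paper's balanced
#'   design is 200/200 and the unbalanced one 320/80 (total fixed at 400).
#' @param sigmaBase baseline overdispersions to sweep.
#' @param deltaFrac \eqn{\Delta\sigma} expressed as fractions of
#'   `sigmaBase` (0 rows estimate the FPR).
#' @param reps sample pairs per grid point (paper value 1000).
#' @param alpha significance level (0.05).
#' @param seed integer seed.
#' @return List of class `"PowerGridSpec"`.
#' @export
powerGridSpec <- function(mu = 1500, groupSizes = list(c(200, 200),
                                                       c(320, 80)),
                          sigmaBase = c(0.05, 0.1, 0.2, 0.4),
                          deltaFrac = c(0, 0.25, 0.5, 1),
                          reps = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(mu > 0, length(sigmaBase) > 0, length(deltaFrac) > 0,
            reps >= 1, alpha > 0, alpha < 1)
  structure(list(mu = mu, groupSizes = groupSizes, sigmaBase = sigmaBase,
                 deltaFrac = deltaFrac, reps = as.integer(reps),
                 alpha = alpha, seed = as.integer(seed)),
            class = "PowerGridSpec")
}

#' Run the power/FPR grid
#'
#' At each (group sizes, \eqn{\sigma}, \eqn{\Delta\sigma}) combination
#' draws `reps` sample pairs with means `mu` and overdispersions
#' \eqn{\sigma} vs \eqn{\sigma + \Delta\sigma} (the larger overdispersion
#' in the second, possibly smaller, group), applies the three tests, and
#' records the fraction of p-values below `alpha` — power when
#' \eqn{\Delta\sigma > 0}, FPR when \eqn{\Delta\sigma = 0}.
#'
#' @param spec a [powerGridSpec()].
#' @return data.frame with columns `test`, `n1`, `n2`, `sigma_base`,
#'   `delta_sigma`, `power_or_fpr`, `mc_se`, `reps`.
#' @export
powerGrid <- function(spec) {
  stopifnot(inherits(spec, "PowerGridSpec"))
  set.seed(spec$seed)
  rows <- list()
  for (gs in spec$groupSizes) {
    for (s0 in spec$sigmaBase) {
      for (df in spec$deltaFrac) {
        delta <- df * s0
        hits <- c(fligner_killeen = 0, levene = 0, nb_lrt = 0)
        used <- c(fligner_killeen = 0, levene = 0, nb_lrt = 0)
        for (r in seq_len(spec$reps)) {
          pair <- drawNBPair(gs[1], gs[2], spec$mu, s0, s0 + delta)
          p <- runThreeTests(pair$y1, pair$y2)
          ok <- !is.na(p)
          used <- used + ok
          hits <- hits + (ok & p < spec$alpha)
        }
        prop <- hits / pmax(used, 1)
        rows[[length(rows) + 1]] <- data.frame(
          test = names(prop), n1 = gs[1], n2 = gs[2], sigma_base = s0,
          delta_sigma = delta, power_or_fpr = unname(prop),
          mc_se = sqrt(unname(prop) * (1 - unname(prop)) / spec$reps),
          reps = spec$reps)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
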