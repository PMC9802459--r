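## Overrepresentation and cross-tissue aggregation: hypergeometric tests,
## the permutation-calibrated Fisher's-combined meta-analysis (the
## hypergeometric test is discrete, so the chi-squared null of classical
## Fisher's method does not hold and the combined statistic is calibrated
## by label permutation instead), the eGene depletion test, and the
## rank-based score comparison.

#' One-sided hypergeometric overrepresentation p-value
#'
#' Upper tail including the observed value:
#' \eqn{P(X \ge overlap)} for \eqn{X \sim}
#' Hypergeometric(universeSize, labelCount, setSize).
#'
#' @param overlap observed number of labeled genes in the set.
#' @param setSize size of the gene set (after intersection with the
#'   universe).
#' @param labelCount number of labeled genes in the universe.
#' @param universeSize universe size.
#' @return p-value.
#' @export
hypergeomTest <- function(overlap, setSize, labelCount, universeSize) {
  if (any(overlap > pmin(setSize, labelCount)) ||
      any(c(setSize, labelCount) > universeSize) || any(overlap < 0))
    stop("inconsistent hypergeometric counts")
  phyper(overlap - 1, labelCount, universeSize - labelCount, setSize,
         lower.tail = FALSE)
}

## Per-tissue machinery shared by the meta-analysis: set membership as a
## sets x genes indicator matrix so each permutation is one matrix-vector
## product plus a vectorized phyper call.
.tissueSetup <- function(labels, sets, targetLabel) {
  universe <- names(labels)
  M <- do.call(rbind, lapply(sets, function(s)
    as.numeric(universe %in% s)))
  setSize <- rowSums(M)
  labeled <- as.numeric(labels == targetLabel)
  list(M = M, setSize = setSize, labeled = labeled,
       labelCount = sum(labeled), universeSize = length(universe))
}

.tissuePvals <- function(setup, labeledVec) {
  overlap <- drop(setup$M %*% labeledVec)
  phyper(overlap - 1, setup$labelCount,
         setup$universeSize - setup$labelCount, setup$setSize,
         lower.tail = FALSE)
}

#' Permutation-calibrated Fisher's-combined overrepresentation meta-analysis
#'
#' For each gene set, per-tissue hypergeometric overrepresentation
#' p-values for `targetLabel` are combined as
#' \eqn{T = -2\sum_t \ln p_t}. Because the hypergeometric test is
#' discrete, \eqn{T} is not \eqn{\chi^2} under the null; instead the gene
#' labels are permuted independently within each tissue, all per-tissue
#' p-values and \eqn{T} recomputed, and the empirical p-value taken as
#' the fraction of permutations with \eqn{T_{perm} \ge T_{obs}}.
#' Per-tissue p-values are floored at the smallest positive double before
#' taking logs. Only tissues with at least `minLabeled` genes of either
#' high-variability label are included.
#'
#' @param labelTables named list (one per tissue) of per-gene labels in
#'   `{"not_sdv", "male_higher", "female_higher"}`, each named by gene;
#'   the names define that tissue's universe.
#' @param sets named list of gene-id vectors (e.g. from [readGMT()]);
#'   intersected with each tissue's universe before testing.
#' @param targetLabel the label tested for overrepresentation.
#' @param B permutations (paper default 10000).
#' @param seed integer seed.
#' @param minLabeled tissue inclusion rule: at least this many
#'   `male_higher` or `female_higher` genes (paper value 20).
#' @return `DataFrame` with one row per set: `set`, `T_obs`, per-tissue
#'   p-values in `metadata()$tissue_p`, `perm_p` and BH-adjusted `q`.
#' @export
fisherCombinedPerm <- function(labelTables, sets, targetLabel,
                               B = 10000L, seed = 1L, minLabeled = 20L) {
  if (B < 100) warning("fewer than 100 permutations: empirical p is coarse")
  keep <- vapply(labelTables, function(lab) {
    sum(lab == "male_higher") >= minLabeled ||
      sum(lab == "female_higher") >= minLabeled
  }, TRUE)
  if (!any(keep)) stop("no tissue passes the inclusion rule")
  labelTables <- labelTables[keep]
  setups <- lapply(labelTables, .tissueSetup, sets = sets,
                   targetLabel = targetLabel)
  eps <- .Machine$double.xmin
  obsP <- vapply(setups, function(st) .tissuePvals(st, st$labeled),
                 numeric(length(sets)))
  obsP <- matrix(obsP, nrow = length(sets))
  Tobs <- rowSums(-2 * log(pmax(obsP, eps)))
  set.seed(seed)
  exceed <- numeric(length(sets))
  for (b in seq_len(B)) {
    Tperm <- numeric(length(sets))
    for (st in setups)
      Tperm <- Tperm - 2 * log(pmax(.tissuePvals(st, sample(st$labeled)),
                                    eps))
    exceed <- exceed + (Tperm >= Tobs)
  }
  permP <- exceed / B
  out <- DataFrame(set = names(sets), T_obs = Tobs, perm_p = permP,
                   q = bhAdjust(permP), row.names = names(sets))
  colnames(obsP) <- names(labelTables)
  rownames(obsP) <- names(sets)
  metadata(out)$tissue_p <- obsP
  metadata(out)$tissues_used <- names(labelTables)
  out
}

#' eGene depletion among SDV genes across tissues
#'
#' Per tissue, cross-tabulates SDV status against eGene status over the
#' shared gene universe, computes the fold enrichment (observed overlap /
#' expected overlap, expected = set sizes' product / universe size) and a
#' two-sided Fisher exact p-value (BH-adjusted across tissues). The
#' median fold across tissues is then tested for depletion by permuting
#' the SDV labels within each tissue: the empirical p-value is the
#' fraction of permutations whose median fold is at least as low as the
#' observed one.
#'
#' @param sdvFlags named list (per tissue) of per-gene logical SDV flags,
#'   named by gene.
#' @param egeneFlags parallel list of per-gene logical eGene flags.
#' @param B permutations (paper default 10000).
#' @param seed integer seed.
#' @param minSdv tissue inclusion rule: at least this many SDV genes in
#'   the shared universe (paper value 20).
#' @return List: `per_tissue` (data.frame: tissue, overlap, n_sdv,
#'   n_egene, universe, fold, fisher_p, q), `median_fold`, `perm_p`.
#' @export
eGeneDepletion <- function(sdvFlags, egeneFlags, B = 10000L, seed = 1L,
                           minSdv = 20L) {
  stopifnot(identical(names(sdvFlags), names(egeneFlags)))
  tabs <- list()
  for (t in names(sdvFlags)) {
    genes <- intersect(names(sdvFlags[[t]]), names(egeneFlags[[t]]))
    sdv <- sdvFlags[[t]][genes]
    eg <- egeneFlags[[t]][genes]
    if (sum(sdv) == 0) {
      warning("tissue '", t, "' has no SDV genes in the universe; dropped")
      next
    }
    if (sum(sdv) < minSdv) next
    tabs[[t]] <- list(sdv = unname(sdv), eg = unname(eg))
  }
  if (length(tabs) == 0) stop("no tissue passes the inclusion rule")
  foldOf <- function(sdv, eg) {
    expected <- sum(sdv) * sum(eg) / length(sdv)
    sum(sdv & eg) / expected
  }
  per <- do.call(rbind, lapply(names(tabs), function(t) {
    sdv <- tabs[[t]]$sdv; eg <- tabs[[t]]$eg
    tab <- table(factor(sdv, c(FALSE, TRUE)), factor(eg, c(FALSE, TRUE)))
    data.frame(tissue = t, overlap = sum(sdv & eg), n_sdv = sum(sdv),
               n_egene = sum(eg), universe = length(sdv),
               fold = foldOf(sdv, eg),
               fisher_p = fisher.test(tab)$p.value)
  }))
  per$q <- bhAdjust(per$fisher_p)
  medObs <- median(per$fold)
  set.seed(seed)
  medPerm <- vapply(seq_len(B), function(b) {
    median(vapply(tabs, function(tt) foldOf(sample(tt$sdv), tt$eg), 0))
  }, 0)
  list(per_tissue = per, median_fold = medObs,
       perm_p = sum(medPerm <= medObs) / B)
}

#' Two-sided rank-sum comparison of two score groups
#'
#' Mann-Whitney U test with tie correction (normal approximation), used
#' to compare constraint or specificity scores between gene groups.
#'
#' @param a,b numeric score vectors.
#' @return Two-sided p-value.
#' @export
scoreRankTest <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty score group")
  wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
              correct = TRUE)$p.value
}
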