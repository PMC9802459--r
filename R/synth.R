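## Synthetic-data generators. These produce every input the analyses need:
## NB count studies with covariate-dependent means and sex-dependent
## overdispersion (with planted SDV genes and global outlier samples),
## gene-set collections with planted enrichment, per-tissue eGene labels
## with planted depletion, and a small labeled single-cell matrix for the
## tau statistic. All output is fully determined by the seed.

#' Configuration for a synthetic expression study
#'
#' @param nGenes number of genes.
#' @param nMale,nFemale exact group sizes (sex is assigned
#'   deterministically, not sampled, so groups are exact).
#' @param baselineLogMuRange per-gene baseline log mean expression, on the
#'   counts-per-million scale (the library-size offset is added on top);
#'   drawn uniformly.
#' @param baselineSigmaRange per-gene baseline overdispersion
#'   \eqn{\sigma} (squared biological CV), drawn uniformly.
#' @param sdvFraction fraction of genes with a planted sex effect on
#'   log overdispersion.
#' @param sdvLogSigmaEffect absolute planted effect on log \eqn{\sigma}
#'   in one sex (sign, i.e. which sex is more variable, is random per gene).
#' @param sbeLogMuEffect planted sex effect on the log mean for the same
#'   planted genes (0 disables sex-biased mean expression).
#' @param covariateEffectScale SD of the per-gene coefficients for the
#'   nuisance covariates (age, RIN, ischemic time, PC1-PC5) on the log
#'   mean, applied to standardized covariates.
#' @param librarySizeRange library sizes, drawn log-uniformly.
#' @param outlierFraction fraction of samples turned into global
#'   expression outliers.
#' @param outlierScale SD of the gene-specific perturbations added to an
#'   outlier sample's log means (a uniform shift would be cancelled by
#'   CPM normalization; real global outliers deviate in profile).
#' @param seed integer seed; fully determines the study.
#' @return A validated list of class `"SynthConfig"`.
#' @export
synthConfig <- function(nGenes = 1000L, nMale = 200L, nFemale = 200L,
                        baselineLogMuRange = log(c(150, 3000)),
                        baselineSigmaRange = c(0.05, 0.15),
                        sdvFraction = 0.1, sdvLogSigmaEffect = 1.5,
                        sbeLogMuEffect = 0, covariateEffectScale = 0.05,
                        librarySizeRange = c(5e5, 2e6),
                        outlierFraction = 0, outlierScale = 0,
                        seed = 1L) {
  stopifnot(nGenes >= 1, nMale >= 0, nFemale >= 0,
            length(baselineLogMuRange) == 2,
            diff(baselineLogMuRange) >= 0,
            length(baselineSigmaRange) == 2, baselineSigmaRange[1] > 0,
            diff(baselineSigmaRange) >= 0,
            sdvFraction >= 0, sdvFraction <= 1,
            outlierFraction >= 0, outlierFraction <= 1,
            librarySizeRange[1] > 0, diff(librarySizeRange) >= 0)
  structure(list(
    nGenes = as.integer(nGenes), nMale = as.integer(nMale),
    nFemale = as.integer(nFemale),
    baselineLogMuRange = baselineLogMuRange,
    baselineSigmaRange = baselineSigmaRange,
    sdvFraction = sdvFraction, sdvLogSigmaEffect = sdvLogSigmaEffect,
    sbeLogMuEffect = sbeLogMuEffect,
    covariateEffectScale = covariateEffectScale,
    librarySizeRange = librarySizeRange,
    outlierFraction = outlierFraction, outlierScale = outlierScale,
    seed = as.integer(seed)), class = "SynthConfig")
}

.covariateNames <- c("age", "RIN", "ischemic_time",
                     "PC1", "PC2", "PC3", "PC4", "PC5")

#' Simulate a bulk RNA-seq study with planted sex effects on variability
#'
#' Draws gene x sample NB counts in which each gene's mean depends on a
#' library-size offset, nuisance covariates and (optionally) sex, and each
#' gene's overdispersion depends on sex for the planted SDV genes:
#' \eqn{\log\mu_{gj} = b_g + x_j^\top\gamma_g + \beta^\mu_g m_j + o_{gj}
#' + \log(L_j/10^6)} and \eqn{\log\sigma_{gj} = \log\sigma_g +
#' \beta^\sigma_g m_j}, with \eqn{m_j} the male indicator and
#' \eqn{o_{gj}} the outlier perturbation (nonzero only for outlier
#' samples). The planted truth is stored in `rowData`.
#'
#' @param config a [synthConfig()] object.
#' @return An [ExpressionStudy-class] with assays `counts`, colData
#'   covariates (including `is_outlier`) and rowData truth.
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  if (config$nMale == 0 || config$nFemale == 0)
    stop("both sexes must be present (sex term unidentifiable otherwise)")
  set.seed(config$seed)
  n <- config$nMale + config$nFemale
  G <- config$nGenes
  sex <- factor(rep(c("female", "male"), c(config$nFemale, config$nMale)),
                levels = c("female", "male"))
  male <- as.numeric(sex == "male")

  covs <- cbind(
    age = runif(n, 20, 70),
    RIN = rnorm(n), ischemic_time = rnorm(n),
    PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
    PC4 = rnorm(n), PC5 = rnorm(n))
  z <- scale(covs)  # effects act on standardized covariates
  libSize <- round(exp(runif(n, log(config$librarySizeRange[1]),
                             log(config$librarySizeRange[2]))))
  nOut <- round(config$outlierFraction * n)
  outlier <- rep(FALSE, n)
  if (nOut > 0) outlier[sample.int(n, nOut)] <- TRUE
  ## outlier samples get gene-specific log-mean perturbations of scale
  ## outlierScale: a uniform shift would be removed exactly by the CPM
  ## normalization downstream, so the profile itself must deviate
  outShift <- matrix(0, G, n)
  if (nOut > 0)
    outShift[, outlier] <- rnorm(G * nOut, 0, config$outlierScale)

  b0 <- runif(G, config$baselineLogMuRange[1], config$baselineLogMuRange[2])
  sigma0 <- runif(G, config$baselineSigmaRange[1],
                  config$baselineSigmaRange[2])
  nSdv <- round(config$sdvFraction * G)
  isSdv <- rep(FALSE, G)
  if (nSdv > 0) isSdv[sample.int(G, nSdv)] <- TRUE
  dirSign <- ifelse(isSdv, sample(c(-1, 1), G, replace = TRUE), 0)
  betaSig <- dirSign * config$sdvLogSigmaEffect
  betaMuSex <- ifelse(isSdv, config$sbeLogMuEffect, 0)
  gamma <- matrix(rnorm(G * ncol(z), 0, config$covariateEffectScale),
                  nrow = G)

  counts <- matrix(0, G, n)
  covPart <- gamma %*% t(z)  # G x n
  logLibTerm <- log(libSize / 1e6)
  for (g in seq_len(G)) {
    logMu <- b0[g] + covPart[g, ] + betaMuSex[g] * male + outShift[g, ] +
      logLibTerm
    sig <- exp(log(sigma0[g]) + betaSig[g] * male)
    counts[g, ] <- rnbinom(n, mu = exp(logMu), size = 1 / sig)
  }
  rownames(counts) <- sprintf("gene%05d", seq_len(G))
  colnames(counts) <- sprintf("sample%04d", seq_len(n))

  sampleData <- DataFrame(
    sex = sex, covs, library_size = libSize, is_outlier = outlier,
    row.names = colnames(counts))
  geneData <- DataFrame(
    gene_id = rownames(counts),
    baseline_log_mu = b0, baseline_sigma = sigma0,
    is_sdv = isSdv,
    sdv_direction = ifelse(dirSign > 0, "male_higher",
                           ifelse(dirSign < 0, "female_higher", "none")),
    true_beta_sigma_sex = betaSig, true_beta_mu_sex = betaMuSex,
    row.names = rownames(counts))
  ExpressionStudy(counts, sampleData, geneData,
                  metadata = list(config = config))
}

#' Simulate gene-set collections with planted enrichment
#'
#' Null sets draw members uniformly from the universe; planted sets draw a
#' fraction `plantedOverlap` of their members from the genes carrying
#' `targetLabel` (the rest uniformly from the remainder).
#'
#' @param nSets total number of sets.
#' @param universe character vector of gene ids.
#' @param labels per-gene labels, named by gene (e.g. `"male_higher"`,
#'   `"female_higher"`, `"not_sdv"`).
#' @param targetLabel the label planted sets are enriched for.
#' @param plantedOverlap fraction in `[0,1]` of planted-set members drawn
#'   from the labeled genes.
#' @param nPlanted number of planted sets (first `nPlanted` sets).
#' @param setSizeRange set sizes drawn uniformly from this integer range.
#' @param seed integer seed.
#' @return Named list of character vectors with attribute `"planted"`
#'   (logical per set); writable with [writeGMT()].
#' @export
simulateGeneSets <- function(nSets, universe, labels, targetLabel,
                             plantedOverlap = 0.8, nPlanted = 0,
                             setSizeRange = c(20, 100), seed = 1L) {
  if (length(universe) == 0) stop("empty gene universe")
  if (plantedOverlap < 0 || plantedOverlap > 1)
    stop("plantedOverlap must lie in [0,1]")
  stopifnot(nPlanted <= nSets)
  set.seed(seed)
  labeled <- names(labels)[labels == targetLabel]
  other <- setdiff(universe, labeled)
  sets <- vector("list", nSets)
  planted <- seq_len(nSets) <= nPlanted
  for (s in seq_len(nSets)) {
    size <- sample(seq(setSizeRange[1], setSizeRange[2]), 1)
    size <- min(size, length(universe))
    if (planted[s] && length(labeled) > 0) {
      k <- min(round(plantedOverlap * size), length(labeled))
      members <- c(sample(labeled, k),
                   sample(other, min(size - k, length(other))))
    } else {
      members <- sample(universe, size)
    }
    sets[[s]] <- unique(members)
  }
  names(sets) <- sprintf("set%03d", seq_len(nSets))
  attr(sets, "planted") <- planted
  sets
}

#' Simulate per-tissue eGene labels with planted depletion among SDV genes
#'
#' Assigns each gene eGene status with
#' \eqn{P(eGene \mid SDV) = f \cdot P(eGene \mid not SDV)} (clipped to
#' `[0,1]`), independently per tissue.
#'
#' @param sdvCalls named list (one element per tissue) of per-gene logical
#'   SDV flags, each named by gene id.
#' @param depletionFactor positive multiplier \eqn{f} (1 = no association,
#'   <1 = depletion).
#' @param baseRate \eqn{P(eGene \mid not SDV)}.
#' @param seed integer seed.
#' @return Named list of per-gene logical eGene flags, parallel to
#'   `sdvCalls`.
#' @export
simulateEGeneLabels <- function(sdvCalls, depletionFactor, baseRate = 0.4,
                                seed = 1L) {
  if (depletionFactor < 0) stop("depletionFactor must be >= 0")
  set.seed(seed)
  pSdv <- min(max(depletionFactor * baseRate, 0), 1)
  lapply(sdvCalls, function(flags) {
    p <- ifelse(flags, pSdv, baseRate)
    setNames(runif(length(flags)) < p, names(flags))
  })
}

#' Simulate a labeled single-cell count matrix with exclusive markers
#'
#' Three (or more) cell types; each type has a block of marker genes
#' expressed only in that type, plus housekeeping genes expressed at a
#' common rate in every cell. Used to exercise pseudo-bulk aggregation and
#' the tau specificity index (markers have tau = 1, housekeeping genes
#' tau near 0).
#'
#' @param nCellsPerType integer vector (>= 1 each), one entry per type.
#' @param nMarkersPerType markers exclusive to each type.
#' @param nHousekeeping genes expressed uniformly across all cells.
#' @param markerRate,hkRate Poisson means per cell for expressed genes.
#' @param seed integer seed.
#' @return List with `counts` (gene x cell integer matrix), `cellType`
#'   (factor per cell) and `geneInfo` (data.frame: gene, class, type).
#' @export
simulateSCCounts <- function(nCellsPerType = c(60, 50, 40),
                             nMarkersPerType = 20, nHousekeeping = 50,
                             markerRate = 5, hkRate = 5, seed = 1L) {
  stopifnot(all(nCellsPerType >= 1))
  set.seed(seed)
  nT <- length(nCellsPerType)
  types <- paste0("type", seq_len(nT))
  cellType <- factor(rep(types, nCellsPerType), levels = types)
  nCells <- length(cellType)
  G <- nT * nMarkersPerType + nHousekeeping
  counts <- matrix(0, G, nCells)
  geneClass <- c(rep(types, each = nMarkersPerType),
                 rep("housekeeping", nHousekeeping))
  for (g in seq_len(G)) {
    if (geneClass[g] == "housekeeping") {
      counts[g, ] <- rpois(nCells, hkRate)
    } else {
      inType <- cellType == geneClass[g]
      counts[g, inType] <- rpois(sum(inType), markerRate)
    }
  }
  rownames(counts) <- c(
    sprintf("marker_%s_%02d", rep(types, each = nMarkersPerType),
            sequence(rep(nMarkersPerType, nT))),
    sprintf("hk_%03d", seq_len(nHousekeeping)))
  colnames(counts) <- sprintf("cell%04d", seq_len(nCells))
  list(counts = counts, cellType = setNames(cellType, colnames(counts)),
       geneInfo = data.frame(gene = rownames(counts), class = geneClass))
}
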