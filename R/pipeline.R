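## Per-tissue SDV discovery: CPM filtering, upper-quartile normalization
## offsets, PCA-based global outlier removal, per-gene dual LRTs against
## the location-scale NB model, BH correction, permutation calibration of
## the sex-dispersion coefficient, and the replication analysis.

#' Counts per million
#'
#' @param counts gene x sample matrix.
#' @param libSize per-sample library sizes (defaults to column sums).
#' @return Matrix of `counts * 1e6 / libSize`, columnwise.
#' @export
computeCPM <- function(counts, libSize = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(libSize <= 0)) stop("sample with zero library size")
  sweep(counts, 2, libSize / 1e6, "/")
}

#' Genes expressed in every sample
#'
#' Keeps a gene iff its CPM is strictly positive in every sample (genes
#' with CPM = 0 in at least one individual are removed).
#'
#' @param cpm CPM matrix from [computeCPM()].
#' @return Character vector of kept gene ids (row names).
#' @export
filterExpressed <- function(cpm) {
  keep <- apply(cpm > 0, 1, all)
  rownames(cpm)[keep]
}

#' Upper-quartile normalization factors
#'
#' Per-sample scale factors from the 75th percentile of counts relative to
#' library size, rescaled so their geometric mean is 1 (edgeR's
#' `"upperquartile"` method of `calcNormFactors`).
#'
#' @param counts gene x sample count matrix (post-filtering).
#' @param libSize library sizes (defaults to column sums).
#' @return Named numeric vector of factors with geometric mean 1.
#' @export
uqNormFactors <- function(counts, libSize = colSums(counts)) {
  counts <- as.matrix(counts)
  expressed <- rowSums(counts) > 0
  uq <- apply(counts[expressed, , drop = FALSE], 2, quantile, probs = 0.75)
  if (any(uq == 0))
    stop("degenerate upper quartile (0) in at least one sample")
  f <- edgeR::calcNormFactors(counts, lib.size = libSize,
                              method = "upperquartile")
  setNames(f, colnames(counts))
}

#' PCA-based global expression outlier detection
#'
#' Runs sample-space PCA on the supplied log2 CPM matrix and flags, for
#' every principal component explaining more than `varShare` of the total
#' variance, samples whose scores lie more than `iqrMult` interquartile
#' ranges above the third quartile or below the first. Single pass (the
#' PCA is not re-run after removal).
#'
#' @param logCPM gene x sample matrix of log2(CPM + 1) values.
#' @param varShare variance-share threshold for a component to be checked.
#' @param iqrMult IQR multiplier of the Tukey fence.
#' @return Character vector of kept sample ids, with the removed ids in
#'   attribute `"removed"`.
#' @export
pcaOutlierSamples <- function(logCPM, varShare = 0.05, iqrMult = 1.5) {
  if (ncol(logCPM) < 3) stop("need at least 3 samples for outlier PCA")
  pc <- prcomp(t(logCPM), center = TRUE, scale. = FALSE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  out <- rep(FALSE, ncol(logCPM))
  for (k in which(share > varShare)) {
    sc <- pc$x[, k]
    q <- quantile(sc, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    out <- out | sc > q[2] + iqrMult * iqr | sc < q[1] - iqrMult * iqr
  }
  kept <- colnames(logCPM)[!out]
  attr(kept, "removed") <- colnames(logCPM)[out]
  kept
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (`stats::p.adjust`).
#'
#' @param p vector of p-values in `[0,1]` (`NA` allowed, propagated).
#' @return Adjusted q-values in `[0,1]`.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Filter, normalize and de-outlier an expression study
#'
#' Applies, in order: CPM computation, removal of genes with CPM = 0 in
#' any sample, PCA-based removal of global outlier samples on
#' log2(CPM + 1), then (on the kept genes x kept samples matrix)
#' recomputed library sizes, upper-quartile normalization factors and the
#' mean-model offset \eqn{\log(\mathrm{library\ size} \times
#' \mathrm{norm\ factor})}.
#'
#' @param study an [ExpressionStudy-class].
#' @param removeOutliers run the PCA outlier step (default TRUE).
#' @param varShare,iqrMult passed to [pcaOutlierSamples()].
#' @return The subset `ExpressionStudy` with an added `cpm` assay, colData
#'   columns `norm_factor` and `offset`, and normalization bookkeeping
#'   (removed samples, filtered gene count) in `metadata(study)$normalization`.
#' @export
normalizeStudy <- function(study, removeOutliers = TRUE, varShare = 0.05,
                           iqrMult = 1.5) {
  stopifnot(is(study, "ExpressionStudy"))
  counts <- assay(study, "counts")
  cpm <- computeCPM(counts)
  keptGenes <- filterExpressed(cpm)
  if (length(keptGenes) == 0) stop("no gene expressed in every sample")
  removed <- character(0)
  keptSamples <- colnames(counts)
  if (removeOutliers) {
    logCPM <- log2(cpm[keptGenes, , drop = FALSE] + 1)
    keptSamples <- pcaOutlierSamples(logCPM, varShare, iqrMult)
    removed <- attr(keptSamples, "removed")
  }
  out <- study[keptGenes, keptSamples]
  sx <- table(sampleSex(out))
  if (any(sx < 3))
    stop("fewer than 3 surviving samples of one sex after outlier removal")
  sub <- assay(out, "counts")
  libSize <- colSums(sub)
  nf <- uqNormFactors(sub, libSize)
  colData(out)$library_size <- libSize
  colData(out)$norm_factor <- nf
  colData(out)$offset <- log(libSize * nf)
  assays(out)$cpm <- computeCPM(sub, libSize)
  metadata(out)$normalization <- list(
    removed_samples = removed, n_genes_in = nrow(study),
    n_genes_kept = length(keptGenes), n_samples_kept = length(keptSamples))
  out
}

## Design matrices for models 1-3. Continuous covariates are standardized
## (location/scale of nuisance covariates does not affect the sex LRTs but
## conditions the optimizer). Sex coding: female = 0 (reference), male = 1.
.designMatrices <- function(meta) {
  male <- as.numeric(factor(as.character(meta$sex),
                            levels = c("female", "male"))) - 1
  covNames <- intersect(.covariateNames, colnames(meta))
  Z <- NULL
  if (length(covNames) > 0) {
    Z <- as.matrix(as.data.frame(meta[, covNames, drop = FALSE]))
    Z <- scale(Z)
    Z[, apply(is.na(Z), 2, any)] <- 0  # constant covariate -> drop effect
  }
  Xfull <- cbind(`(Intercept)` = 1, sexmale = male, Z)
  Xnosex <- cbind(`(Intercept)` = 1, Z)
  list(full = Xfull, nosex = Xnosex)
}

#' Dual LRTs for one gene under the NB location-scale model
#'
#' Fits model 1 (sex + covariates on both the log mean and the log
#' overdispersion, library-size offset on the mean), model 2 (sex dropped
#' from the overdispersion) and model 3 (sex dropped from the mean), and
#' computes the two 1-df likelihood-ratio tests
#' \eqn{p_{\sigma,sex}} (model 1 vs 2) and \eqn{p_{\mu,sex}} (model 1 vs 3).
#'
#' @param y counts for one gene across samples.
#' @param meta per-sample metadata (columns `sex` and any of
#'   age/RIN/ischemic_time/PC1..PC5).
#' @param offset mean-model offset, typically from [normalizeStudy()].
#' @param control optimizer control passed to [nbFit()].
#' @param designs optional precomputed design-matrix pair (internal; built
#'   from `meta` when NULL).
#' @return List: `beta_sigma_sex`, `beta_mu_sex`, `p_sigma_sex`,
#'   `p_mu_sex`, `converged` (all three fits), and `fit1` (the model 1
#'   [NBFit-class], used to warm-start permutations).
#' @export
testGene <- function(y, meta, offset, control = list(), designs = NULL) {
  X <- if (is.null(designs)) .designMatrices(meta) else designs
  ctl <- modifyList(.nbCtlDefaults, control)
  y <- as.numeric(y)
  if (any(y < 0)) stop("negative counts")
  pm <- ncol(X$full)
  d1 <- list(y = y, Xmu = X$full, Xsigma = X$full, offset = offset)
  r1 <- .nbFitCore(y, X$full, X$full, offset,
                   .nbStart(d1), ctl)
  keep <- which(colnames(X$full) != "sexmale")
  sexCol <- which(colnames(X$full) == "sexmale")
  b1mu <- r1$beta[seq_len(pm)]
  b1sig <- r1$beta[pm + seq_len(pm)]
  r2 <- .nbFitCore(y, X$full, X$nosex, offset, c(b1mu, b1sig[keep]), ctl)
  r3 <- .nbFitCore(y, X$nosex, X$full, offset, c(b1mu[keep], b1sig), ctl)
  conv <- r1$converged && r2$converged && r3$converged
  pSig <- pMu <- NA_real_
  if (conv) {
    pSig <- pchisq(max(2 * (r1$loglik - r2$loglik), 0), 1,
                   lower.tail = FALSE)
    pMu <- pchisq(max(2 * (r1$loglik - r3$loglik), 0), 1,
                  lower.tail = FALSE)
  }
  fit1 <- new("NBFit",
              betaMu = setNames(b1mu, colnames(X$full)),
              betaSigma = setNames(b1sig, colnames(X$full)),
              logLik = r1$loglik, converged = isTRUE(r1$converged),
              nIter = as.integer(r1$iter), gradNorm = r1$gradnorm)
  list(beta_sigma_sex = b1sig[sexCol], beta_mu_sex = b1mu[sexCol],
       p_sigma_sex = pSig, p_mu_sex = pMu, converged = conv, fit1 = fit1)
}

#' Permutation calibration of the sex-dispersion coefficient
#'
#' Shuffles the sex labels only (all other covariates stay attached to
#' their samples), refits model 1, and records the permuted
#' \eqn{\beta_{\sigma,sex}}. The empirical p-value is the fraction of
#' retained permutations with \eqn{|\beta_{perm}| > |\beta_{obs}|}
#' (strict inequality, no smoothing). Non-converged permutation fits are
#' dropped from the null; if more than 20% are dropped the result is
#' flagged unreliable.
#'
#' @param y,meta,offset as in [testGene()].
#' @param betaObs observed \eqn{\beta_{\sigma,sex}} from model 1.
#' @param B number of permutations (paper default 1000).
#' @param seed integer seed for the label shuffles.
#' @param warmStart optional [NBFit-class] (the observed model 1 fit) used
#'   to start each permutation refit.
#' @param control optimizer control.
#' @param designs optional precomputed design-matrix pair (internal).
#' @return List: `perm_p`, `n_used`, `reliable`.
#' @export
permutationTest <- function(y, meta, offset, betaObs, B = 1000L,
                            seed = 1L, warmStart = NULL,
                            control = list(), designs = NULL) {
  X <- if (is.null(designs)) .designMatrices(meta) else designs
  ctl <- modifyList(.nbCtlDefaults, control)
  y <- as.numeric(y)
  sexCol <- which(colnames(X$full) == "sexmale")
  pm <- ncol(X$full)
  start <- if (!is.null(warmStart))
    c(betaMu(warmStart), betaSigma(warmStart))
  else .nbStart(list(y = y, Xmu = X$full, Xsigma = X$full,
                     offset = offset))
  set.seed(seed)
  betaPerm <- nb_perm_beta(y, X$full, offset, start, sexCol, B,
                           maxit = ctl$maxit, reltol = ctl$reltol,
                           gradtol = ctl$gradTol)
  betaPerm[is.nan(betaPerm)] <- NA_real_
  used <- sum(!is.na(betaPerm))
  reliable <- used >= 0.8 * B
  if (!reliable)
    warning("more than 20% of permutation fits failed to converge")
  p <- if (used == 0) NA_real_ else
    sum(abs(betaPerm[!is.na(betaPerm)]) > abs(betaObs)) / used
  list(perm_p = p, n_used = used, reliable = reliable)
}

#' SDVResults: per-gene results of the SDV discovery procedure
#'
#' A `DataFrame` subclass with one row per tested gene and columns
#' `gene_id`, `beta_sigma_sex`, `beta_mu_sex`, `p_sigma_sex`, `p_mu_sex`,
#' `q_sigma_sex`, `q_mu_sex`, `perm_p`, `perm_q`, `is_sdv`, `direction`,
#' `converged`.
#' @export
setClass("SDVResults", contains = "DFrame")

#' Apply the SDV decision rule
#'
#' A gene is called SDV iff its BH-adjusted LRT p-value
#' (`q_sigma_sex`) and its BH-adjusted permutation p-value (`perm_q`) are
#' both below `alpha` and all its fits converged. Direction is the sign
#' of \eqn{\beta_{\sigma,sex}} under female = 0 / male = 1 coding
#' (positive = `male_higher`).
#'
#' @param results an [SDVResults-class] (or DataFrame with its columns).
#' @param alpha FDR threshold (default 0.05).
#' @return `results` with `is_sdv` and `direction` filled in.
#' @export
callSDV <- function(results, alpha = 0.05) {
  qs <- results$q_sigma_sex
  pq <- results$perm_q
  ok <- !is.na(qs) & qs < alpha & !is.na(pq) & pq < alpha &
    results$converged
  results$is_sdv <- ok
  results$direction <- ifelse(!ok, "none",
                              ifelse(results$beta_sigma_sex > 0,
                                     "male_higher", "female_higher"))
  results
}

#' Run the full per-tissue SDV discovery procedure
#'
#' Normalizes the study ([normalizeStudy()]), fits the three NB
#' location-scale models per gene ([testGene()]), BH-adjusts the two LRT
#' p-value vectors over all converged genes, runs the permutation test
#' ([permutationTest()]) on genes passing the `q_sigma_sex < alpha`
#' screen, BH-adjusts the empirical p-values over the screened genes, and
#' applies the SDV decision rule ([callSDV()]).
#'
#' @param study an [ExpressionStudy-class].
#' @param B permutations per screened gene (paper default 1000).
#' @param alpha FDR threshold for both the screen and the final call.
#' @param seed integer seed (drives the permutation shuffles).
#' @param normalize set FALSE if `study` already carries `offset`.
#' @param permScope BH scope for the empirical p-values: `"screened"`
#'   (default; adjusted over genes entering the permutation stage) or
#'   `"all"` (adjusted over all tested genes, non-screened genes set to
#'   p = 1).
#' @param control optimizer control for all fits.
#' @param removeOutliers passed to [normalizeStudy()].
#' @return An [SDVResults-class]; normalization bookkeeping and the call
#'   parameters are in `metadata()`.
#' @export
runSDVPipeline <- function(study, B = 1000L, alpha = 0.05, seed = 1L,
                           normalize = TRUE, permScope = c("screened", "all"),
                           control = list(), removeOutliers = TRUE) {
  permScope <- match.arg(permScope)
  if (normalize)
    study <- normalizeStudy(study, removeOutliers = removeOutliers)
  counts <- assay(study, "counts")
  meta <- colData(study)
  offset <- meta$offset
  if (is.null(offset)) stop("study carries no offset; run normalizeStudy")
  G <- nrow(counts)
  X <- .designMatrices(meta)
  res <- vector("list", G)
  for (g in seq_len(G))
    res[[g]] <- testGene(counts[g, ], meta, offset, control = control,
                         designs = X)
  out <- DataFrame(
    gene_id = rownames(counts),
    beta_sigma_sex = vapply(res, `[[`, 0, "beta_sigma_sex"),
    beta_mu_sex = vapply(res, `[[`, 0, "beta_mu_sex"),
    p_sigma_sex = vapply(res, `[[`, 0, "p_sigma_sex"),
    p_mu_sex = vapply(res, `[[`, 0, "p_mu_sex"),
    converged = vapply(res, `[[`, TRUE, "converged"),
    row.names = rownames(counts))
  out$q_sigma_sex <- bhAdjust(out$p_sigma_sex)
  out$q_mu_sex <- bhAdjust(out$p_mu_sex)

  screened <- which(out$converged & !is.na(out$q_sigma_sex) &
                      out$q_sigma_sex < alpha)
  out$perm_p <- NA_real_
  out$perm_reliable <- NA
  set.seed(seed)
  permSeeds <- sample.int(2^31 - 1, G)  # one permutation stream per gene
  for (g in screened) {
    pt <- permutationTest(counts[g, ], meta, offset,
                          betaObs = out$beta_sigma_sex[g], B = B,
                          seed = permSeeds[g],
                          warmStart = res[[g]]$fit1, control = control,
                          designs = X)
    out$perm_p[g] <- pt$perm_p
    out$perm_reliable[g] <- pt$reliable
  }
  out$perm_q <- NA_real_
  if (permScope == "screened") {
    out$perm_q[screened] <- bhAdjust(out$perm_p[screened])
  } else {
    pAll <- ifelse(is.na(out$perm_p), 1, out$perm_p)
    out$perm_q <- bhAdjust(pAll)
    out$perm_q[setdiff(seq_len(G), screened)] <- NA_real_
  }
  out <- callSDV(out, alpha)
  metadata(out) <- c(metadata(study)["normalization"],
                     list(alpha = alpha, B = B, seed = seed,
                          permScope = permScope))
  new("SDVResults", out)
}

#' Discovery/replication split analysis
#'
#' Splits samples into discovery and replication sets stratified by sex,
#' runs the full SDV procedure on the discovery set, and checks each
#' discovery call in the replication set: a gene replicates iff its
#' replication-set LRT p-value and permutation p-value are both below
#' `nominal` and the more-variable sex agrees between the two sets.
#'
#' @param study an [ExpressionStudy-class].
#' @param split fraction of each sex placed in the discovery set.
#' @param B permutations for the discovery pipeline.
#' @param repB permutations used per gene in the replication set.
#' @param alpha discovery FDR threshold; `nominal` replication threshold.
#' @param nominal nominal p threshold in the replication set (0.05).
#' @param seed integer seed (split + permutations).
#' @param scoreAllGenes also compute replication status for every
#'   discovery-tested gene (needed for [nullReplicationRate()]); costly.
#' @param ... passed to [runSDVPipeline()].
#' @return List: `discovery` (SDVResults), `replication` (DataFrame of
#'   discovery calls with replication columns), `rate` (replicated /
#'   discovered; `NaN` when nothing is discovered), and, when
#'   `scoreAllGenes`, `replicated_all` (named logical over all tested
#'   genes).
#' @export
replicationAnalysis <- function(study, split = 0.7, B = 1000L,
                                repB = 1000L, alpha = 0.05,
                                nominal = 0.05, seed = 1L,
                                scoreAllGenes = FALSE, ...) {
  stopifnot(split > 0, split < 1)
  sex <- sampleSex(study)
  set.seed(seed)
  disc <- unlist(lapply(split(seq_len(ncol(study)), sex), function(idx) {
    sample(idx, round(split * length(idx)))
  }))
  repl <- setdiff(seq_len(ncol(study)), disc)
  if (min(table(sex[disc])) < 10 || min(table(sex[repl])) < 10)
    stop("each split must retain at least 10 samples of each sex")

  discRes <- runSDVPipeline(study[, disc], B = B, alpha = alpha,
                            seed = seed + 1L, ...)
  replStudy <- normalizeStudy(study[, repl])
  counts <- assay(replStudy, "counts")
  meta <- colData(replStudy)

  scoreGene <- function(gid, discBeta, permSeed) {
    if (!(gid %in% rownames(counts))) return(NA)
    y <- counts[gid, ]
    tg <- testGene(y, meta, meta$offset)
    if (!tg$converged || is.na(tg$p_sigma_sex)) return(NA)
    if (tg$p_sigma_sex >= nominal) return(FALSE)
    if (sign(tg$beta_sigma_sex) != sign(discBeta)) return(FALSE)
    pt <- permutationTest(y, meta, meta$offset, tg$beta_sigma_sex,
                          B = repB, seed = permSeed, warmStart = tg$fit1)
    isTRUE(pt$perm_p < nominal)
  }

  set.seed(seed + 2L)
  permSeeds <- setNames(sample.int(2^31 - 1, nrow(discRes)),
                        discRes$gene_id)
  discovered <- discRes$gene_id[discRes$is_sdv]
  repFlags <- vapply(discovered, function(gid) {
    scoreGene(gid, discRes[gid, "beta_sigma_sex"], permSeeds[[gid]])
  }, NA)
  rate <- if (length(discovered) == 0) NaN else
    mean(repFlags, na.rm = TRUE)

  outcome <- list(
    discovery = discRes,
    replication = DataFrame(gene_id = discovered, replicated = repFlags),
    rate = rate,
    discovery_samples = colnames(study)[disc],
    replication_samples = colnames(study)[repl])
  if (scoreAllGenes) {
    allFlags <- vapply(discRes$gene_id, function(gid) {
      scoreGene(gid, discRes[gid, "beta_sigma_sex"], permSeeds[[gid]])
    }, NA)
    outcome$replicated_all <- setNames(allFlags, discRes$gene_id)
  }
  outcome
}

#' Null distribution of the replication rate under random gene sampling
#'
#' Repeatedly samples `drawSize` genes uniformly from all discovery-tested
#' genes and computes the fraction that replicate, giving the replication
#' rate expected if the discovery procedure were picking genes at random.
#'
#' @param replicated named logical vector of replication status for every
#'   discovery-tested gene (from [replicationAnalysis()] with
#'   `scoreAllGenes = TRUE`; `NA` = not scorable, excluded from draws).
#' @param drawSize genes per draw (typically the number of discovery
#'   calls).
#' @param nDraws number of random draws (paper default 10000).
#' @param seed integer seed.
#' @return List: `rates` (length `nDraws`) and `median`.
#' @export
nullReplicationRate <- function(replicated, drawSize, nDraws = 10000L,
                                seed = 1L) {
  replicated <- replicated[!is.na(replicated)]
  if (drawSize > length(replicated))
    stop("drawSize exceeds the number of scorable genes")
  set.seed(seed)
  rates <- vapply(seq_len(nDraws), function(i) {
    mean(replicated[sample.int(length(replicated), drawSize)])
  }, 0)
  list(rates = rates, median = median(rates))
}
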