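#' ExpressionStudy: counts plus sample metadata (and optional planted truth)
#'
#' An `ExpressionStudy` is a [SummarizedExperiment::SummarizedExperiment]
#' holding a gene x sample matrix of nonnegative integer counts in the
#' `"counts"` assay, per-sample covariates in `colData` (at minimum a
#' `sex` factor with levels `female`, `male`; typically also `age`, `RIN`,
#' `ischemic_time` and genotype PCs `PC1`..`PC5`, plus `library_size`),
#' and per-gene annotation in `rowData`. Synthetic studies additionally
#' carry the planted ground truth in `rowData` (columns `is_sdv`,
#' `sdv_direction`, `true_beta_sigma_sex`, `true_beta_mu_sex`).
#'
#' @seealso [simulateStudy()], [normalizeStudy()], [runSDVPipeline()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.validExpressionStudy <- function(object) {
  msg <- NULL
  if (!("counts" %in% names(assays(object))))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  if (!("sex" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain a 'sex' column")
  else {
    sx <- colData(object)$sex
    if (!all(as.character(sx) %in% c("female", "male")))
      msg <- c(msg, "sex must take values 'female'/'male'")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionStudy", .validExpressionStudy)

#' Construct an ExpressionStudy
#'
#' @param counts gene x sample matrix of nonnegative integer counts.
#' @param sampleData data.frame/DataFrame of per-sample covariates; must
#'   contain `sex` (`"female"`/`"male"`). A `library_size` column is added
#'   from the column sums when absent.
#' @param geneData optional per-gene DataFrame (truth columns for synthetic
#'   studies).
#' @param metadata optional list stored in the object metadata.
#' @return An [ExpressionStudy-class] object.
#' @export
ExpressionStudy <- function(counts, sampleData, geneData = NULL,
                            metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  sampleData <- as(sampleData, "DataFrame")
  if (!("library_size" %in% colnames(sampleData)))
    sampleData$library_size <- colSums(counts)
  if (is.null(geneData))
    geneData <- DataFrame(gene_id = rownames(counts))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = sampleData, rowData = geneData, metadata = metadata)
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy Sex factor of the samples (levels
#'   female, male; male is the non-reference level in all models).
#' @param x,object An `ExpressionStudy`.
#' @export
sampleSex <- function(x) {
  factor(as.character(colData(x)$sex), levels = c("female", "male"))
}

#' @describeIn ExpressionStudy Planted-truth table (`NULL` for real data).
#' @export
studyTruth <- function(x) {
  rd <- rowData(x)
  if (!("is_sdv" %in% colnames(rd))) return(NULL)
  rd[, intersect(c("gene_id", "is_sdv", "sdv_direction",
                   "true_beta_sigma_sex", "true_beta_mu_sex"),
                 colnames(rd)), drop = FALSE]
}

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy with", nrow(object), "genes x", ncol(object),
      "samples\n")
  sx <- table(sampleSex(object))
  cat("  sex: ", sx[["female"]], " female / ", sx[["male"]], " male\n",
      sep = "")
  if (!is.null(studyTruth(object)))
    cat("  synthetic truth: ", sum(rowData(object)$is_sdv),
        " planted SDV genes\n", sep = "")
  invisible(NULL)
})

#' NBFit: a fitted negative binomial location-scale regression
#'
#' Holds the maximum-likelihood coefficients for the mean (`betaMu`, log
#' link, with offset) and the overdispersion (`betaSigma`, log link), the
#' maximized log-likelihood, and convergence diagnostics.
#'
#' @slot betaMu numeric, named coefficients on the log-mean scale.
#' @slot betaSigma numeric, named coefficients on the log-overdispersion
#'   scale.
#' @slot logLik numeric(1) maximized log-likelihood.
#' @slot converged logical(1).
#' @slot nIter integer(1) function evaluations used by the optimizer.
#' @slot gradNorm numeric(1) max absolute gradient at the optimum.
#' @export
setClass("NBFit", representation(
  betaMu = "numeric", betaSigma = "numeric", logLik = "numeric",
  converged = "logical", nIter = "integer", gradNorm = "numeric"))

#' @describeIn NBFit maximized log-likelihood
#' @param object,x An `NBFit`.
#' @export
setMethod("logLik", "NBFit", function(object) object@logLik)

#' @describeIn NBFit mean-model coefficients (log scale)
#' @export
betaMu <- function(x) x@betaMu

#' @describeIn NBFit overdispersion-model coefficients (log scale)
#' @export
betaSigma <- function(x) x@betaSigma

#' @describeIn NBFit whether the optimizer met its convergence criteria
#' @export
isConverged <- function(x) x@converged

setMethod("show", "NBFit", function(object) {
  cat("NBFit (negative binomial location-scale regression)\n")
  cat("  logLik:", format(object@logLik, digits = 8),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  beta_mu:   ", paste(names(object@betaMu),
                             signif(object@betaMu, 4),
                             sep = "=", collapse = ", "), "\n")
  cat("  beta_sigma:", paste(names(object@betaSigma),
                             signif(object@betaSigma, 4),
                             sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})
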