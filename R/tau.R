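## Pseudo-bulk aggregation of labeled single-cell counts and the tau
## cell-type-specificity index.

#' Pseudo-bulk aggregation and per-type CPM
#'
#' Sums raw counts within each cell type, then converts each pseudo-bulk
#' vector to CPM (vector * 1e6 / sum(vector)) and log2-transforms with a
#' pseudocount of 1.
#'
#' @param counts gene x cell integer matrix.
#' @param cellType per-cell labels (factor or character), one per column.
#' @return List: `counts` (gene x type summed counts), `cpm`,
#'   `logCPM` (log2(CPM + 1)).
#' @export
pseudoBulk <- function(counts, cellType) {
  counts <- as.matrix(counts)
  if (length(cellType) != ncol(counts))
    stop("one cell-type label per cell is required")
  if (any(is.na(cellType))) stop("unlabeled cells present")
  cellType <- factor(cellType)
  if (nlevels(cellType) < 2) stop("at least 2 cell types are required")
  agg <- t(rowsum(t(counts), cellType))
  cpm <- sweep(agg, 2, colSums(agg) / 1e6, "/")
  list(counts = agg, cpm = cpm, logCPM = log2(cpm + 1))
}

#' Tau specificity index
#'
#' \eqn{\tau = \sum_i (1 - \hat x_i) / (n - 1)} with
#' \eqn{\hat x = x / \max(x)}: 0 for uniform expression, 1 for
#' expression exclusive to one context.
#'
#' @param x nonnegative expression vector across contexts (or a gene x
#'   context matrix, handled rowwise).
#' @return tau in `[0,1]`; `NA` for all-zero vectors.
#' @export
tauIndex <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, tauIndex))
  if (any(x < 0)) stop("expression must be nonnegative")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Cell-type specificity of every gene from labeled single-cell counts
#'
#' Convenience wrapper: [pseudoBulk()] then [tauIndex()] on the per-type
#' expression profiles.
#'
#' @inheritParams pseudoBulk
#' @param transform expression scale for tau: `"log2p1"` (default,
#'   log2(CPM + 1); zero CPM is representable) or `"cpm"` (raw CPM, the
#'   alternative dialect).
#' @return Named numeric vector of per-gene tau values.
#' @export
cellTypeTau <- function(counts, cellType, transform = c("log2p1", "cpm")) {
  transform <- match.arg(transform)
  pb <- pseudoBulk(counts, cellType)
  tauIndex(if (transform == "log2p1") pb$logCPM else pb$cpm)
}
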