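#' @describeIn log2Transform replace the \code{"intensity"} assay by its
#'   base-2 logarithm; errors if any cell is non-positive, naming the first
#'   offending cell.
#' @export
setMethod("log2Transform", "ProbeLevelSet", function(x) {
  if (assayNames(x) == "log2") return(x)
  m <- assay(x, "intensity")
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive intensity at row '%s', array '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  out <- x
  SummarizedExperiment::assays(out) <- list(log2 = log2(m))
  out
})

#' @describeIn quantileNormalize matrix method; every column becomes a
#'   rank-preserving rearrangement of the mean order-statistic reference,
#'   with ties within a column receiving the mean of the reference values at
#'   their tied ranks.
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (any(!is.finite(x))) stop("input must be finite and dense")
  if (ncol(x) == 1L) return(x)
  limma::normalizeQuantiles(x, ties = TRUE)
})

#' @describeIn quantileNormalize normalize the \code{"log2"} assay across
#'   arrays.
#' @export
setMethod("quantileNormalize", "ProbeLevelSet", function(x, ...) {
  if (assayNames(x) != "log2")
    stop("quantile normalization operates on the log2 assay; ",
         "call log2Transform() first")
  out <- x
  m <- quantileNormalize(assay(x, "log2"))
  dimnames(m) <- dimnames(assay(x))
  SummarizedExperiment::assays(out) <- list(log2 = m)
  out
})

## One alternating-median polish of a probes x arrays block.
## Returns the per-array summary overall + column effect, with the probe
## (row) effects recentred to median zero so the decomposition is unique.
.polishBlock <- function(z, maxIter, tol) {
  if (nrow(z) == 1L) return(list(expr = drop(z), single = TRUE))
  mp <- stats::medpolish(z, eps = tol, maxiter = maxIter,
                         trace.iter = FALSE, na.rm = FALSE)
  rowShift <- stats::median(mp$row)
  list(expr = mp$overall + rowShift + mp$col, single = FALSE,
       residuals = mp$residuals)
}

#' @describeIn summarizeMedianPolish fit overall + probe + array effects per
#'   probe set by alternating median sweeps (Tukey median polish, the RMA
#'   summarization step); the probe-set expression on an array is the
#'   overall effect plus that array's effect, with probe effects constrained
#'   to median zero. Probe sets with a single probe are passed through with
#'   a message.
#' @export
setMethod("summarizeMedianPolish", "ProbeLevelSet",
          function(x, maxIter = 10L, tol = 0.01, ...) {
  if (assayNames(x) != "log2")
    stop("median-polish summarization operates on the log2 assay; ",
         "call log2Transform() first")
  m <- assay(x, "log2")
  ps <- as.character(rowData(x)$probeSetId)
  genes <- unique(ps)
  idx <- split(seq_len(nrow(m)), factor(ps, levels = genes))
  expr <- matrix(NA_real_, length(genes), ncol(m),
                 dimnames = list(genes, colnames(m)))
  nSingle <- 0L
  for (i in seq_along(idx)) {
    res <- .polishBlock(m[idx[[i]], , drop = FALSE], maxIter, tol)
    if (res$single) nSingle <- nSingle + 1L
    expr[i, ] <- res$expr
  }
  if (nSingle)
    message(nSingle, " probe set(s) had a single probe; values passed",
            " through without polishing")
  new("ExpressionMatrix",
      SummarizedExperiment(assays = list(exprs = expr),
                           colData = colData(x)))
})

#' Full probe-level preprocessing: log2, quantile normalize, median polish
#'
#' Convenience wrapper chaining [log2Transform()], [quantileNormalize()] and
#' [summarizeMedianPolish()] — the quantile-normalization and median-polish
#' steps of the RMA pipeline (its convolution background correction is
#' intentionally not applied; see the package vignette).
#'
#' @param probes a \linkS4class{ProbeLevelSet} on the intensity scale.
#' @param normalize logical; set \code{FALSE} to skip between-array quantile
#'   normalization.
#' @param maxIter,tol median-polish controls.
#' @return an \linkS4class{ExpressionMatrix} of log2 expression.
#' @examples
#' sim <- simulateProbeData(SimConfig(nProbeSets = 30, seed = 2))
#' expr <- rmaSummarize(sim$probes)
#' dim(expr)
#' @export
rmaSummarize <- function(probes, normalize = TRUE, maxIter = 10L,
                         tol = 0.01) {
  x <- log2Transform(probes)
  if (normalize) x <- quantileNormalize(x)
  summarizeMedianPolish(x, maxIter = maxIter, tol = tol)
}
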