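## 5'/3' block bounds for n probe positions: the first and last
## floor((n-1)/2) positions, middle excluded. Degenerates to 1-5 / 7-11 for
## the canonical 11-probe set.
.biasBlocks <- function(nPos) {
  k <- floor((nPos - 1) / 2)
  if (k < 1L) stop("bias statistic needs at least 3 probe positions")
  list(five = seq_len(k), three = seq(nPos - k + 1L, nPos))
}

#' @describeIn probePositionBias for each probe set and array, the median
#'   log2 signal over the 5'-most probes (positions 1-5 of 11) minus the
#'   median over the 3'-most probes (positions 7-11); the middle probe is
#'   unused. Positive values indicate 5' bias, negative values 3' bias
#'   (higher signal nearer the transcript's 3' end, the signature of
#'   incomplete in vitro transcription).
#' @export
setMethod("probePositionBias", "ProbeLevelSet", function(x, ...) {
  if (assayNames(x) != "log2")
    stop("the bias statistic is defined on log2 data; ",
         "call log2Transform() first")
  m <- assay(x, "log2")
  pos <- rowData(x)$probePosition
  ps <- as.character(rowData(x)$probeSetId)
  nPos <- length(unique(pos))
  blocks <- .biasBlocks(nPos)

  ord <- order(factor(ps, levels = unique(ps)), pos)
  m <- m[ord, , drop = FALSE]
  genes <- unique(ps)
  nG <- length(genes)
  ## rows are now gene-major, position-sorted: reshape to positions x
  ## (genes * arrays) and take column medians per block
  arr <- array(m, dim = c(nPos, nG, ncol(m)))
  med5 <- apply(arr[blocks$five, , , drop = FALSE], c(2, 3), stats::median)
  med3 <- apply(arr[blocks$three, , , drop = FALSE], c(2, 3), stats::median)
  bias <- med5 - med3
  dimnames(bias) <- list(genes, colnames(m))
  new("BiasTable",
      SummarizedExperiment(assays = list(bias = bias), colData = colData(x)))
})

#' Mean 5'/3' bias per group of arrays
#'
#' Pools the per-(probe set, array) bias values of every array in a group
#' and averages them. More negative means stronger 3' bias; on real
#' protocol comparisons the two-cycle group sits well below the one-cycle
#' and IVT-Express groups.
#'
#' @param bias a \linkS4class{BiasTable}.
#' @param by grouping of arrays: \code{"protocol"}, \code{"array"}, or
#'   \code{"tissue_protocol"}.
#' @return data.frame with columns \code{group}, \code{meanBias} and
#'   \code{n} (bias values pooled). Groups with no arrays are absent from
#'   the output rather than reported as zero.
#' @examples
#' sim <- simulateProbeData(SimConfig(nProbeSets = 40, seed = 5))
#' bt <- probePositionBias(log2Transform(sim$probes))
#' meanBias(bt, by = "protocol")
#' @export
meanBias <- function(bias, by = c("protocol", "array", "tissue_protocol")) {
  stopifnot(is(bias, "BiasTable"))
  by <- match.arg(by)
  cd <- colData(bias)
  grp <- switch(by,
    protocol = as.character(cd$protocol),
    array = colnames(bias),
    tissue_protocol = paste(cd$tissue, cd$protocol, sep = "_"))
  b <- assay(bias, "bias")
  levels <- unique(grp)
  out <- do.call(rbind, lapply(levels, function(g) {
    v <- as.vector(b[, grp == g, drop = FALSE])
    data.frame(group = g, meanBias = mean(v), n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Trimmed quantile curves of the bias distribution per protocol
#'
#' Empirical quantiles of the pooled per-(probe set, array) bias values for
#' each protocol, restricted to probabilities in [0.05, 0.95] because the
#' extreme biases are very large and would dominate an untrimmed plot.
#' Quantiles use linear interpolation between order statistics
#' (\code{\link[stats]{quantile}} type 7).
#'
#' @param bias a \linkS4class{BiasTable}.
#' @param qGrid probabilities, all within [0.05, 0.95].
#' @param by grouping of arrays (as in [meanBias()]).
#' @return data.frame with columns \code{group}, \code{q}, \code{value};
#'   within a group \code{value} is non-decreasing in \code{q}.
#' @examples
#' sim <- simulateProbeData(SimConfig(nProbeSets = 40, seed = 5))
#' bt <- probePositionBias(log2Transform(sim$probes))
#' head(trimmedQuantileCurve(bt, qGrid = c(0.05, 0.5, 0.95)))
#' @export
trimmedQuantileCurve <- function(bias, qGrid = seq(0.05, 0.95, by = 0.01),
                                 by = c("protocol", "array",
                                        "tissue_protocol")) {
  stopifnot(is(bias, "BiasTable"))
  by <- match.arg(by)
  if (any(qGrid < 0.05 | qGrid > 0.95))
    stop("qGrid probabilities must lie within [0.05, 0.95] (trimmed curve)")
  if (is.unsorted(qGrid, strictly = TRUE))
    stop("qGrid must be strictly increasing")
  cd <- colData(bias)
  grp <- switch(by,
    protocol = as.character(cd$protocol),
    array = colnames(bias),
    tissue_protocol = paste(cd$tissue, cd$protocol, sep = "_"))
  b <- assay(bias, "bias")
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    v <- as.vector(b[, grp == g, drop = FALSE])
    data.frame(group = g, q = qGrid,
               value = unname(stats::quantile(v, probs = qGrid, type = 7)))
  }))
  rownames(out) <- NULL
  out
}
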