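#' Log2-transform probe-level intensities
#'
#' @param x a \linkS4class{ProbeLevelSet} on the linear intensity scale.
#' @return a \linkS4class{ProbeLevelSet} with a single \code{"log2"} assay.
#' @export
setGeneric("log2Transform", function(x) standardGeneric("log2Transform"))

#' Quantile-normalize log2 probe-level data across arrays
#'
#' @param x a \linkS4class{ProbeLevelSet} with a \code{"log2"} assay, or a
#'   numeric matrix (rows = probes, columns = arrays).
#' @param ... unused.
#' @return object of the same class with every array forced onto the common
#'   reference distribution (the mean of per-rank order statistics).
#' @export
setGeneric("quantileNormalize", function(x, ...)
  standardGeneric("quantileNormalize"))

#' Summarize probe-level log2 data to probe-set expression by median polish
#'
#' @param x a \linkS4class{ProbeLevelSet} with a \code{"log2"} assay.
#' @param maxIter maximum alternating median sweeps (default 10).
#' @param tol convergence tolerance on row/column residual medians, log2
#'   units (default 0.01).
#' @param ... unused.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
setGeneric("summarizeMedianPolish", function(x, maxIter = 10L, tol = 0.01, ...)
  standardGeneric("summarizeMedianPolish"))

#' Compute the per-probe-set 5'/3' probe-position bias statistic
#'
#' @param x a \linkS4class{ProbeLevelSet} with a \code{"log2"} assay.
#' @param ... unused.
#' @return a \linkS4class{BiasTable}.
#' @export
setGeneric("probePositionBias", function(x, ...)
  standardGeneric("probePositionBias"))

#' Probe-set identifiers
#' @param x a package data container.
#' @return character vector of probe-set ids.
#' @export
setGeneric("probeSetIds", function(x) standardGeneric("probeSetIds"))

#' Array metadata (tissue, protocol, replicate)
#' @param x a package data container.
#' @return a \link[S4Vectors]{DataFrame} of per-array metadata.
#' @export
setGeneric("arrayInfo", function(x) standardGeneric("arrayInfo"))

#' Consensus over-amplified probe sets
#' @param x an \linkS4class{AmplificationCallSet}.
#' @return character vector of probe-set ids.
#' @export
setGeneric("consensusOver", function(x) standardGeneric("consensusOver"))

#' Consensus under-amplified probe sets
#' @param x an \linkS4class{AmplificationCallSet}.
#' @return character vector of probe-set ids.
#' @export
setGeneric("consensusUnder", function(x) standardGeneric("consensusUnder"))

#' Studentised residuals of a pairwise protocol fit
#' @param x a \linkS4class{PairwiseFit}.
#' @return named numeric vector of externally studentised residuals.
#' @export
setGeneric("studentized", function(x) standardGeneric("studentized"))
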