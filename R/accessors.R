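#' Construct a simulation configuration
#'
#' User-facing constructor for \linkS4class{SimConfig} with the study-design
#' defaults: 2000 probe sets of 11 probes, two tissues (MS, EZ), three
#' labelling protocols in three biological replicates, protocol-specific 3'
#' gradients (two-cycle the steepest), and 20 + 20 planted over-/under-
#' amplified genes with |log2 shift| drawn uniformly from [2, 6] that act
#' only on two-cycle arrays.
#'
#' @param nProbeSets,nProbesPerSet,tissues,protocols,nReplicates design
#'   dimensions; see \linkS4class{SimConfig}.
#' @param baselineMean,baselineSd,affinitySd,tissueEffectSd,noiseSd
#'   log2-scale effect magnitudes.
#' @param gradient named numeric of per-protocol 3' gradients (log2 units
#'   across the full probe span).
#' @param nOver,nUnder,shiftLow,shiftHigh planted mis-amplification design.
#' @param seed integer seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(nProbeSets = 100, seed = 7)
#' cfg
#' @export
SimConfig <- function(nProbeSets = 2000L,
                      nProbesPerSet = 11L,
                      tissues = c("MS", "EZ"),
                      protocols = c("one_cycle", "two_cycle", "ivt_e"),
                      nReplicates = 3L,
                      baselineMean = 8,
                      baselineSd = 2,
                      affinitySd = 0.7,
                      gradient = c(one_cycle = 0.25, two_cycle = 1.2,
                                   ivt_e = 0.4),
                      tissueEffectSd = 1,
                      nOver = 20L,
                      nUnder = 20L,
                      shiftLow = 2,
                      shiftHigh = 6,
                      noiseSd = 0.25,
                      seed = 1L) {
  new("SimConfig",
      nProbeSets = as.integer(nProbeSets),
      nProbesPerSet = as.integer(nProbesPerSet),
      tissues = as.character(tissues),
      protocols = as.character(protocols),
      nReplicates = as.integer(nReplicates),
      baselineMean = baselineMean, baselineSd = baselineSd,
      affinitySd = affinitySd, gradient = gradient,
      tissueEffectSd = tissueEffectSd,
      nOver = as.integer(nOver), nUnder = as.integer(nUnder),
      shiftLow = shiftLow, shiftHigh = shiftHigh,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @describeIn probeSetIds unique probe-set ids in row order.
#' @export
setMethod("probeSetIds", "ProbeLevelSet", function(x)
  unique(as.character(rowData(x)$probeSetId)))

#' @describeIn probeSetIds row names of the expression matrix.
#' @export
setMethod("probeSetIds", "ExpressionMatrix", function(x) rownames(x))

#' @describeIn probeSetIds row names of the bias table.
#' @export
setMethod("probeSetIds", "BiasTable", function(x) rownames(x))

#' @describeIn arrayInfo per-array metadata of a probe-level container.
#' @export
setMethod("arrayInfo", "SummarizedExperiment", function(x)
  colData(x)[, intersect(c("tissue", "protocol", "replicate"),
                         colnames(colData(x))), drop = FALSE])

#' @describeIn consensusOver accessor.
#' @export
setMethod("consensusOver", "AmplificationCallSet", function(x) x@consensusOver)

#' @describeIn consensusUnder accessor.
#' @export
setMethod("consensusUnder", "AmplificationCallSet", function(x)
  x@consensusUnder)

#' @describeIn studentized accessor.
#' @export
setMethod("studentized", "PairwiseFit", function(x) x@studentized)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nProbeSets, "probe sets x",
      object@nProbesPerSet, "probes\n")
  cat("  design:", length(object@tissues), "tissues x",
      length(object@protocols), "protocols x",
      object@nReplicates, "replicates\n")
  cat("  gradients (log2/span):",
      paste(names(object@gradient), signif(object@gradient, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  planted:", object@nOver, "over,", object@nUnder,
      "under, |shift| in [", object@shiftLow, ",", object@shiftHigh,
      "]; noiseSd =", object@noiseSd, "; seed =", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@overGenes), "planted over,",
      length(object@underGenes), "planted under (seed",
      object@seed, ")\n")
})

setMethod("show", "PairwiseFit", function(object) {
  cat(sprintf("PairwiseFit: %s ~ %s [%s rep %d], n = %d\n",
              object@test, object@reference, object@tissue,
              object@replicate, object@n))
  cat(sprintf("  slope %.4f, intercept %.4f\n",
              object@slope, object@intercept))
})

setMethod("show", "AmplificationCallSet", function(object) {
  cat("AmplificationCallSet:", length(object@fits), "fits, threshold",
      object@threshold, "\n")
  cat("  consensus:", length(object@consensusOver), "over-amplified,",
      length(object@consensusUnder), "under-amplified",
      sprintf("(>= %d replicates per comparison, %s reading)\n",
              object@minReplicates,
              if (object@strict) "strict" else "pooled"))
  if (length(object@discordant))
    cat("  discordant (excluded):", length(object@discordant), "\n")
})

#' Planted shifts of a simulation truth
#' @param truth a \linkS4class{SimTruth}.
#' @return named numeric of signed log2 shifts.
#' @export
plantedShifts <- function(truth) {
  stopifnot(is(truth, "SimTruth"))
  truth@shifts
}

#' Planted over-/under-amplified gene ids
#' @param truth a \linkS4class{SimTruth}.
#' @return list with elements \code{over} and \code{under}.
#' @export
plantedGenes <- function(truth) {
  stopifnot(is(truth, "SimTruth"))
  list(over = truth@overGenes, under = truth@underGenes)
}
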