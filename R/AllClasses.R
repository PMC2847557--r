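#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

.PROTOCOLS <- c("one_cycle", "two_cycle", "ivt_e")
.TISSUES <- c("MS", "EZ")

#' Simulation configuration for probe-level array data
#'
#' Parameters of the generative model used by [simulateProbeData()]. All
#' effects live on the log2 scale; intensities are obtained by
#' exponentiation. The defaults emulate a two-tissue (root meristem "MS" and
#' elongation zone "EZ"), three-protocol (one-cycle, two-cycle, IVT-Express),
#' three-replicate labelling-protocol comparison on an 11-probe-per-set
#' expression array, with a protocol-specific linear 3' gradient and a
#' planted set of genes whose signal is shifted up or down only under
#' two-cycle amplification.
#'
#' @slot nProbeSets number of probe sets (genes) to simulate.
#' @slot nProbesPerSet probes per probe set; position 1 is nearest the 5'
#'   end of the transcript, position \code{nProbesPerSet} nearest the 3' end.
#' @slot tissues character vector of tissue labels.
#' @slot protocols character vector of protocol labels.
#' @slot nReplicates biological replicates per (tissue, protocol).
#' @slot baselineMean,baselineSd log2-scale location and scale of true gene
#'   expression.
#' @slot affinitySd log2-scale SD of per-probe affinity offsets.
#' @slot gradient named numeric, one entry per protocol: log2 units gained
#'   across the full 5'-to-3' probe span (positive = stronger signal at the
#'   3' end, i.e. 3' bias).
#' @slot tissueEffectSd log2-scale SD of gene-by-tissue effects.
#' @slot nOver,nUnder numbers of planted over-/under-amplified genes.
#' @slot shiftLow,shiftHigh bounds of the absolute planted log2 shift,
#'   applied only under the two-cycle protocol.
#' @slot noiseSd log2-scale replicate noise SD (independent per cell).
#' @slot seed integer seed; the generator is deterministic given the seed.
#'
#' @seealso [SimConfig()] for the user constructor.
#' @export
setClass("SimConfig",
  representation(
    nProbeSets = "integer",
    nProbesPerSet = "integer",
    tissues = "character",
    protocols = "character",
    nReplicates = "integer",
    baselineMean = "numeric",
    baselineSd = "numeric",
    affinitySd = "numeric",
    gradient = "numeric",
    tissueEffectSd = "numeric",
    nOver = "integer",
    nUnder = "integer",
    shiftLow = "numeric",
    shiftHigh = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nProbeSets < 1L) msg <- c(msg, "nProbeSets must be positive")
  if (object@nProbesPerSet < 1L) msg <- c(msg, "nProbesPerSet must be positive")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be positive")
  if (length(object@tissues) < 1L || anyDuplicated(object@tissues))
    msg <- c(msg, "tissues must be a non-empty set of unique labels")
  if (length(object@protocols) < 1L || anyDuplicated(object@protocols))
    msg <- c(msg, "protocols must be a non-empty set of unique labels")
  if (object@nOver + object@nUnder > object@nProbeSets)
    msg <- c(msg, "nOver + nUnder must not exceed nProbeSets")
  if (object@nOver > 0L || object@nUnder > 0L) {
    if (!(object@shiftLow > 0 && object@shiftHigh > 0))
      msg <- c(msg, "shiftLow and shiftHigh must be > 0")
    if (object@shiftLow > object@shiftHigh)
      msg <- c(msg, "shiftLow must not exceed shiftHigh")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@affinitySd < 0) msg <- c(msg, "affinitySd must be >= 0")
  if (object@baselineSd < 0) msg <- c(msg, "baselineSd must be >= 0")
  if (object@tissueEffectSd < 0) msg <- c(msg, "tissueEffectSd must be >= 0")
  if (!all(object@protocols %in% names(object@gradient)))
    msg <- c(msg, "gradient must name an entry for every protocol")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth of a simulated probe-level dataset
#'
#' Records which probe sets were planted as over- or under-amplified under
#' the two-cycle protocol, their signed log2 shifts, the per-protocol 3'
#' gradient magnitudes, and the seed, so that downstream calls can be scored
#' against truth.
#'
#' @slot overGenes,underGenes character vectors of planted probe-set ids
#'   (disjoint; positive and negative planted shift respectively).
#' @slot shifts named numeric of signed log2 shifts for planted genes.
#' @slot gradients named numeric, per-protocol gradient magnitudes.
#' @slot seed integer seed used for generation.
#' @export
setClass("SimTruth",
  representation(
    overGenes = "character",
    underGenes = "character",
    shifts = "numeric",
    gradients = "numeric",
    seed = "integer"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  if (length(intersect(object@overGenes, object@underGenes)))
    msg <- c(msg, "overGenes and underGenes must be disjoint")
  if (!all(sort(names(object@shifts)) ==
           sort(c(object@overGenes, object@underGenes))))
    msg <- c(msg, "shifts must be named by exactly the planted genes")
  if (any(object@shifts[object@overGenes] <= 0))
    msg <- c(msg, "over genes must have positive shifts")
  if (any(object@shifts[object@underGenes] >= 0))
    msg <- c(msg, "under genes must have negative shifts")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Probe-level intensity container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are (probe set, probe
#' position) pairs and whose columns are arrays. \code{rowData} carries
#' \code{probeSetId} and \code{probePosition} (1 = nearest 5' end);
#' \code{colData} carries \code{tissue}, \code{protocol} and
#' \code{replicate}. The single assay is either \code{"intensity"}
#' (linear scale, strictly positive) or \code{"log2"}.
#'
#' @export
setClass("ProbeLevelSet", contains = "SummarizedExperiment")

setValidity("ProbeLevelSet", function(object) {
  msg <- character()
  rd <- rowData(object)
  cd <- colData(object)
  if (!all(c("probeSetId", "probePosition") %in% colnames(rd)))
    return("rowData must contain probeSetId and probePosition")
  if (!all(c("tissue", "protocol", "replicate") %in% colnames(cd)))
    return("colData must contain tissue, protocol and replicate")
  if (length(assayNames(object)) != 1L ||
      !assayNames(object) %in% c("intensity", "log2"))
    return("exactly one assay named 'intensity' or 'log2' is required")
  pos <- rd$probePosition
  tab <- table(rd$probeSetId)
  npos <- length(unique(pos))
  if (length(unique(tab)) != 1L || unique(tab) != npos)
    msg <- c(msg, "every probe set must carry the full position complement")
  if (!all(sort(unique(pos)) == seq_len(npos)))
    msg <- c(msg, "probe positions must be 1..n with no gaps")
  if (assayNames(object) == "intensity" &&
      any(assay(object) <= 0))
    msg <- c(msg, "intensities must be strictly positive")
  if (any(!is.finite(assay(object))))
    msg <- c(msg, "assay values must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Summarized probe-set expression container
#'
#' A \linkS4class{SummarizedExperiment} of probe-set by array log2
#' expression (assay \code{"exprs"}), as produced by median-polish
#' summarization. Values reported on the natural scale (for comparison with
#' published expression levels) are \code{2^exprs}.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (length(assayNames(object)) != 1L || assayNames(object) != "exprs")
    return("exactly one assay named 'exprs' is required")
  if (any(!is.finite(assay(object))))
    return("expression values must be finite")
  TRUE
})

#' Per-probe-set, per-array 5'/3' bias values
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"bias"}: rows
#' are probe sets, columns arrays, values the probe-position bias statistic
#' median(log2, probes 1-5) - median(log2, probes 7-11) on an 11-probe set.
#' Positive values indicate 5' bias, negative values 3' bias.
#'
#' @export
setClass("BiasTable", contains = "SummarizedExperiment")

setValidity("BiasTable", function(object) {
  if (length(assayNames(object)) != 1L || assayNames(object) != "bias")
    return("exactly one assay named 'bias' is required")
  TRUE
})

#' Ordinary least-squares fit between two protocols
#'
#' One log2-vs-log2 regression of a test-protocol array on a
#' reference-protocol array over matched probe sets, with residuals and
#' externally studentised residuals. The test protocol is the response, so
#' a large positive studentised residual means the probe set is higher in
#' the test (two-cycle) data than the cross-protocol trend predicts.
#'
#' @slot reference,test protocol labels of regressor and response arrays.
#' @slot tissue,replicate identity of the matched array pair.
#' @slot slope,intercept OLS coefficients.
#' @slot residuals named numeric, ordinary residuals per probe set.
#' @slot studentized named numeric, externally studentised residuals.
#' @slot n number of probe sets used.
#' @export
setClass("PairwiseFit",
  representation(
    reference = "character",
    test = "character",
    tissue = "character",
    replicate = "integer",
    slope = "numeric",
    intercept = "numeric",
    residuals = "numeric",
    studentized = "numeric",
    n = "integer"
  )
)

setValidity("PairwiseFit", function(object) {
  msg <- character()
  if (length(object@residuals) != object@n)
    msg <- c(msg, "residual vector length must equal n")
  if (length(object@studentized) &&
      length(object@studentized) != object@n)
    msg <- c(msg, "studentized vector length must equal n")
  if (length(object@studentized) && any(!is.finite(object@studentized)))
    msg <- c(msg, "studentised residuals must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-fit amplification calls and their consensus
#'
#' Collects the over/under/none classification of every probe set in every
#' (comparison, tissue, replicate) fit, together with the consensus
#' mis-amplified gene lists. A gene reaches consensus when it is called in
#' the same direction in at least \code{minReplicates} replicates within
#' each of the two comparisons against the two-cycle data.
#'
#' @slot calls data.frame with columns probeSetId, comparison, tissue,
#'   replicate, studentized, class (over/under/none).
#' @slot fits list of \linkS4class{PairwiseFit} objects.
#' @slot threshold studentised-residual threshold used (strict inequality).
#' @slot minReplicates replicates required per comparison for consensus.
#' @slot strict logical; TRUE = the replicate quorum applies within each
#'   comparison, FALSE = pooled across comparisons with at least one call in
#'   each.
#' @slot consensusOver,consensusUnder character vectors of consensus ids.
#' @slot discordant probe sets excluded for conflicting directions.
#' @export
setClass("AmplificationCallSet",
  representation(
    calls = "data.frame",
    fits = "list",
    threshold = "numeric",
    minReplicates = "integer",
    strict = "logical",
    consensusOver = "character",
    consensusUnder = "character",
    discordant = "character"
  )
)

setValidity("AmplificationCallSet", function(object) {
  msg <- character()
  if (object@threshold <= 0) msg <- c(msg, "threshold must be positive")
  if (length(intersect(object@consensusOver, object@consensusUnder)))
    msg <- c(msg, "consensus over and under sets must be disjoint")
  need <- c("probeSetId", "comparison", "tissue", "replicate",
            "studentized", "class")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, "calls must have columns probeSetId, comparison, tissue, replicate, studentized, class")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
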