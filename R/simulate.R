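#' Simulate a probe-level labelling-protocol comparison with ground truth
#'
#' Generates probe-level intensities under an additive log2-scale model and
#' exponentiates. For gene \eqn{g}, tissue \eqn{t}, protocol \eqn{k},
#' replicate \eqn{r} and probe position \eqn{p} (1 = 5'-most):
#' \deqn{y = \theta_g + \tau_{gt} + \phi_{gp} +
#'       \delta_k (p - p_{mid})/\mathrm{span} + s_g 1[k = two\_cycle] +
#'       \epsilon}
#' with \eqn{\theta_g \sim N(baselineMean, baselineSd)}, gene-by-tissue
#' effects \eqn{\tau_{gt} \sim N(0, tissueEffectSd)}, probe affinities
#' \eqn{\phi_{gp} \sim N(0, affinitySd)}, \eqn{p_{mid} = (1+n)/2},
#' \eqn{\mathrm{span} = (n-1)/2}, planted shift \eqn{s_g} (zero for
#' unplanted genes) and i.i.d. cell noise
#' \eqn{\epsilon \sim N(0, noiseSd)}. Intensities are \eqn{2^y} floored at 1
#' so the log2 transform stays defined under extreme draws. A positive
#' gradient \eqn{\delta_k} raises signal towards the 3' end, producing the
#' 3'-bias signature that two-cycle amplification exaggerates.
#'
#' The generator is bit-reproducible for a given configuration: the RNG
#' state is set from \code{config@seed} and restored on exit.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a list with elements \code{probes} (a
#'   \linkS4class{ProbeLevelSet}) and \code{truth} (a
#'   \linkS4class{SimTruth}).
#' @examples
#' sim <- simulateProbeData(SimConfig(nProbeSets = 50, seed = 3))
#' sim$probes
#' plantedGenes(sim$truth)$over
#' @export
simulateProbeData <- function(config = SimConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config@seed)

  nG <- config@nProbeSets
  nP <- config@nProbesPerSet
  genes <- sprintf("ps%05d", seq_len(nG))
  tissues <- config@tissues
  protocols <- config@protocols
  nR <- config@nReplicates

  theta <- stats::rnorm(nG, config@baselineMean, config@baselineSd)
  tau <- matrix(stats::rnorm(nG * length(tissues), 0, config@tissueEffectSd),
                nG, length(tissues), dimnames = list(genes, tissues))
  phi <- matrix(stats::rnorm(nG * nP, 0, config@affinitySd), nG, nP)

  shifts <- numeric(0)
  overGenes <- underGenes <- character(0)
  nPlant <- config@nOver + config@nUnder
  if (nPlant > 0L) {
    planted <- sample(genes, nPlant)
    overGenes <- planted[seq_len(config@nOver)]
    underGenes <- setdiff(planted, overGenes)
    mag <- stats::runif(nPlant, config@shiftLow, config@shiftHigh)
    shifts <- mag * ifelse(planted %in% overGenes, 1, -1)
    names(shifts) <- planted
  }
  sVec <- stats::setNames(numeric(nG), genes)
  sVec[names(shifts)] <- shifts

  pMid <- (1 + nP) / 2
  span <- if (nP > 1L) (nP - 1) / 2 else 1

  gIdx <- rep(seq_len(nG), each = nP)
  pIdx <- rep(seq_len(nP), times = nG)
  rowBase <- theta[gIdx] + phi[cbind(gIdx, pIdx)]
  posTerm <- (pIdx - pMid) / span

  arrays <- expand.grid(replicate = seq_len(nR), protocol = protocols,
                        tissue = tissues, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  arrays <- arrays[, c("tissue", "protocol", "replicate")]
  arrayIds <- with(arrays, paste(tissue, protocol,
                                 paste0("r", replicate), sep = "_"))

  y <- matrix(0, nG * nP, nrow(arrays))
  for (j in seq_len(nrow(arrays))) {
    k <- arrays$protocol[j]
    col <- rowBase + tau[cbind(gIdx, match(arrays$tissue[j], tissues))] +
      config@gradient[[k]] * posTerm
    if (k == "two_cycle") col <- col + sVec[gIdx]
    if (config@noiseSd > 0)
      col <- col + stats::rnorm(nG * nP, 0, config@noiseSd)
    y[, j] <- col
  }
  intens <- pmax(2^y, 1)
  dimnames(intens) <- list(paste(genes[gIdx], pIdx, sep = "_p"), arrayIds)

  rd <- DataFrame(probeSetId = genes[gIdx], probePosition = pIdx,
                  row.names = rownames(intens))
  cd <- DataFrame(tissue = arrays$tissue, protocol = arrays$protocol,
                  replicate = as.integer(arrays$replicate),
                  row.names = arrayIds)
  probes <- new("ProbeLevelSet",
                SummarizedExperiment(assays = list(intensity = intens),
                                     rowData = rd, colData = cd))
  truth <- new("SimTruth", overGenes = overGenes, underGenes = underGenes,
               shifts = shifts, gradients = config@gradient,
               seed = config@seed)
  validObject(probes)
  validObject(truth)
  list(probes = probes, truth = truth)
}
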