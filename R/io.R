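## Shared TSV schema:
##   probe table : probe_set_id, probe_position, then one column per array
##   array table : array_id, tissue, protocol, replicate
##   expression  : probe_set_id, then one column per array (log2 values)
##   truth       : probe_set_id, class (over|under), log2_shift
##   gene list   : one probe_set_id per line

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.readArrayTable <- function(path) {
  d <- .readTsv(path)
  need <- c("array_id", "tissue", "protocol", "replicate")
  if (!all(need %in% names(d)))
    stop("array metadata must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a probe-level dataset from TSV
#'
#' @param probesPath probe table: columns \code{probe_set_id},
#'   \code{probe_position}, then one intensity column per array.
#' @param arraysPath array metadata: \code{array_id}, \code{tissue},
#'   \code{protocol}, \code{replicate}.
#' @return a \linkS4class{ProbeLevelSet} (intensity scale).
#' @export
readProbeTable <- function(probesPath, arraysPath) {
  d <- .readTsv(probesPath)
  if (!all(c("probe_set_id", "probe_position") %in% names(d)))
    stop("probe table must start with probe_set_id and probe_position")
  meta <- .readArrayTable(arraysPath)
  arrayCols <- setdiff(names(d), c("probe_set_id", "probe_position"))
  missing <- setdiff(arrayCols, meta$array_id)
  if (length(missing))
    stop("array column(s) without metadata: ",
         paste(missing, collapse = ", "))
  ## denseness check with a named offender
  tab <- table(d$probe_set_id, d$probe_position)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "probe table is not dense: probe set '%s' has %d row(s) at position %s",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]))
  }
  ord <- order(factor(d$probe_set_id, levels = unique(d$probe_set_id)),
               d$probe_position)
  d <- d[ord, ]
  m <- as.matrix(d[, arrayCols, drop = FALSE])
  rownames(m) <- paste(d$probe_set_id, d$probe_position, sep = "_p")
  meta <- meta[match(arrayCols, meta$array_id), ]
  probes <- new("ProbeLevelSet", SummarizedExperiment(
    assays = list(intensity = m),
    rowData = DataFrame(probeSetId = d$probe_set_id,
                        probePosition = as.integer(d$probe_position),
                        row.names = rownames(m)),
    colData = DataFrame(tissue = meta$tissue, protocol = meta$protocol,
                        replicate = as.integer(meta$replicate),
                        row.names = meta$array_id)))
  validObject(probes)
  probes
}

#' Write a probe-level dataset (and its array metadata) as TSV
#'
#' @param probes a \linkS4class{ProbeLevelSet}.
#' @param probesPath,arraysPath output paths.
#' @return invisibly, the probe table path.
#' @export
writeProbeTable <- function(probes, probesPath, arraysPath) {
  stopifnot(is(probes, "ProbeLevelSet"))
  rd <- rowData(probes)
  d <- data.frame(probe_set_id = rd$probeSetId,
                  probe_position = rd$probePosition,
                  as.data.frame(assay(probes)), check.names = FALSE)
  utils::write.table(d, probesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- colData(probes)
  meta <- data.frame(array_id = rownames(cd), tissue = cd$tissue,
                     protocol = cd$protocol, replicate = cd$replicate)
  utils::write.table(meta, arraysPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(probesPath)
}

#' Read a summarized expression matrix from TSV
#'
#' @param path expression table: \code{probe_set_id} column then one log2
#'   column per array.
#' @param arraysPath array metadata TSV (see [readProbeTable()]).
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, arraysPath) {
  d <- .readTsv(path)
  if (!"probe_set_id" %in% names(d))
    stop("expression table must have a probe_set_id column")
  meta <- .readArrayTable(arraysPath)
  arrayCols <- setdiff(names(d), "probe_set_id")
  missing <- setdiff(arrayCols, meta$array_id)
  if (length(missing))
    stop("array column(s) without metadata: ",
         paste(missing, collapse = ", "))
  m <- as.matrix(d[, arrayCols, drop = FALSE])
  rownames(m) <- d$probe_set_id
  meta <- meta[match(arrayCols, meta$array_id), ]
  out <- new("ExpressionMatrix", SummarizedExperiment(
    assays = list(exprs = m),
    colData = DataFrame(tissue = meta$tissue, protocol = meta$protocol,
                        replicate = as.integer(meta$replicate),
                        row.names = meta$array_id)))
  validObject(out)
  out
}

#' Write a summarized expression matrix as TSV
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeExpression <- function(expr, path) {
  stopifnot(is(expr, "ExpressionMatrix"))
  d <- data.frame(probe_set_id = rownames(expr),
                  as.data.frame(assay(expr)), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene list as plain text, one probe-set id per line
#' @param genes character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a plain-text gene list
#' @param path input path.
#' @return character vector of ids (empty lines dropped).
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Write simulation ground truth as TSV
#' @param truth a \linkS4class{SimTruth}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  g <- c(truth@overGenes, truth@underGenes)
  d <- data.frame(probe_set_id = g,
                  class = ifelse(g %in% truth@overGenes, "over", "under"),
                  log2_shift = unname(truth@shifts[g]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full protocol-comparison pipeline
#'
#' Chains simulation (or a supplied probe-level dataset), preprocessing,
#' bias statistics, mis-amplification calling, concordance and the
#' per-protocol tissue DE comparison, optionally writing every stage's TSV
#' outputs, and returns a machine-readable summary. When ground truth is
#' available the summary includes a recovery confusion matrix.
#'
#' @param config a \linkS4class{SimConfig} used when \code{probes} is NULL.
#' @param probes optional \linkS4class{ProbeLevelSet} to analyse instead of
#'   simulating.
#' @param truth optional \linkS4class{SimTruth} for scoring.
#' @param outDir optional directory; when given, all stage outputs are
#'   written there as TSV / plain text.
#' @param threshold,minReplicates,strict mis-amplification parameters.
#' @param fcThreshold,fdrLevel DE parameters.
#' @return list with elements \code{expr}, \code{bias}, \code{meanBias},
#'   \code{calls}, \code{callCounts}, \code{r2}, \code{pca}, \code{de},
#'   \code{venn} and \code{summary} (consensus sizes, expected vs observed
#'   exceedances, and recovery measures when truth is known).
#' @examples
#' res <- runPipeline(SimConfig(nProbeSets = 150, nOver = 2, nUnder = 2,
#'                              seed = 9))
#' res$summary$consensusOverSize
#' @export
runPipeline <- function(config = SimConfig(), probes = NULL, truth = NULL,
                        outDir = NULL, threshold = 3.5,
                        minReplicates = 2L, strict = TRUE,
                        fcThreshold = 2, fdrLevel = 0.05) {
  if (is.null(probes)) {
    sim <- simulateProbeData(config)
    probes <- sim$probes
    truth <- sim$truth
  }
  normed <- quantileNormalize(log2Transform(probes))
  expr <- summarizeMedianPolish(normed)
  bias <- probePositionBias(normed)
  mb <- meanBias(bias, by = "protocol")
  calls <- callAmplification(expr, threshold = threshold,
                             minReplicates = minReplicates, strict = strict)
  counts <- callCounts(calls)
  r2 <- pairwiseR2Matrix(expr)
  pca <- pcaScores(expr, nComponents = 3L)
  de <- deByProtocol(expr, fcThreshold = fcThreshold, fdrLevel = fdrLevel)
  venn <- vennCounts3(lapply(de, `[[`, "genes"))

  summary <- list(
    nProbeSets = nrow(expr),
    consensusOverSize = length(consensusOver(calls)),
    consensusUnderSize = length(consensusUnder(calls)),
    expectedNullPerFit = expectedExceedances(nrow(expr),
                                             threshold)$expected,
    observedExceedancesPerFit = counts$nOver + counts$nUnder,
    deSetSizes = venn$sizes,
    tripleOverlap = venn$triple,
    triplePct = venn$triplePct)
  if (!is.null(truth)) {
    over <- truth@overGenes; under <- truth@underGenes
    tp <- length(intersect(over, consensusOver(calls))) +
      length(intersect(under, consensusUnder(calls)))
    signErrors <- length(intersect(over, consensusUnder(calls))) +
      length(intersect(under, consensusOver(calls)))
    fp <- length(setdiff(c(consensusOver(calls), consensusUnder(calls)),
                         c(over, under)))
    planted <- length(over) + length(under)
    summary$recovery <- list(
      planted = planted, recovered = tp,
      recoveryRate = if (planted) tp / planted else NA_real_,
      signErrors = signErrors, falsePositives = fp)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    writeProbeTable(probes, p("probes.tsv"), p("arrays.tsv"))
    if (!is.null(truth)) writeSimTruth(truth, p("truth.tsv"))
    writeExpression(expr, p("expression.tsv"))
    biasTab <- data.frame(probe_set_id = rownames(bias),
                          as.data.frame(assay(bias)), check.names = FALSE)
    utils::write.table(biasTab, p("bias.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(mb, p("mean_bias.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(counts, p("call_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(calls@calls, p("calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeGeneList(consensusOver(calls), p("consensus_over.txt"))
    writeGeneList(consensusUnder(calls), p("consensus_under.txt"))
    utils::write.table(data.frame(array_id = rownames(r2),
                                  as.data.frame(r2), check.names = FALSE),
                       p("r2.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (k in names(de))
      utils::write.table(de[[k]]$table, p(paste0("de_", k, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(probes = probes, truth = truth, expr = expr, bias = bias,
       meanBias = mb, calls = calls, callCounts = counts, r2 = r2,
       pca = pca, de = de, venn = venn, summary = summary)
}
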