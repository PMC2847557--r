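#' Ordinary least-squares fit of one protocol's log2 expression on another
#'
#' Fits \eqn{y = a + b x} over matched probe sets, with the test protocol
#' (conventionally the two-cycle sample) as the response so that a positive
#' residual means the probe set is higher in the test data than the
#' cross-protocol trend predicts (over-amplified), and a negative residual
#' lower (under-amplified).
#'
#' @param x reference-protocol log2 expression vector (named by probe set).
#' @param y test-protocol log2 expression vector, same probe sets in the
#'   same order.
#' @param reference,test protocol labels recorded on the fit.
#' @param tissue,replicate identity of the matched array pair.
#' @return a \linkS4class{PairwiseFit} with residuals and externally
#'   studentised residuals.
#' @examples
#' x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
#' fitPairwise(x, 2 * x + 1)@slope
#' @export
fitPairwise <- function(x, y, reference = "one_cycle", test = "two_cycle",
                        tissue = NA_character_, replicate = NA_integer_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("at least 3 matched probe sets are required")
  if (!is.null(names(x)) && !is.null(names(y)) && !all(names(x) == names(y)))
    stop("x and y must be matched on the same probe sets in the same order")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate fit: reference values have zero variance")
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  e <- y - a - b * x
  fit <- new("PairwiseFit", reference = reference, test = test,
             tissue = as.character(tissue),
             replicate = as.integer(replicate),
             slope = b, intercept = a,
             residuals = stats::setNames(e, names(x)),
             studentized = numeric(0), n = as.integer(n))
  fit@studentized <- studentize(fit, x)
  validObject(fit)
  fit
}

#' Externally studentised residuals of a pairwise fit
#'
#' Deletion (leave-one-out) studentisation: \eqn{t_i = e_i / (s_{(i)}
#' \sqrt{1 - h_{ii}})} with hat diagonal \eqn{h_{ii} = 1/n + (x_i -
#' \bar x)^2 / S_{xx}} and \eqn{s_{(i)}^2 = (SSE - e_i^2/(1-h_{ii}))/(n-3)}
#' the residual scale re-estimated without observation \eqn{i}. Under the
#' Normal null these follow a t distribution on \eqn{n - 3} degrees of
#' freedom, indistinguishable from a standard Normal at the tens of
#' thousands of probe sets of a whole-array fit. If every residual is zero
#' (an exact fit) all studentised residuals are defined as zero, with a
#' message.
#'
#' @param fit a \linkS4class{PairwiseFit}.
#' @param x the reference-protocol vector the fit was computed from
#'   (needed for the leverages).
#' @return named numeric vector of studentised residuals.
#' @export
studentize <- function(fit, x) {
  stopifnot(is(fit, "PairwiseFit"))
  n <- fit@n
  if (n < 4L) stop("external studentisation requires n >= 4")
  e <- fit@residuals
  if (all(e == 0)) {
    message("exact fit: all studentised residuals defined as 0")
    return(stats::setNames(numeric(n), names(e)))
  }
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  sse <- sum(e^2)
  s2i <- (sse - e^2 / (1 - h)) / (n - 3)
  s2i[s2i < 0] <- 0  # numerical guard; exact-outlier observation
  t <- e / (sqrt(s2i) * sqrt(1 - h))
  t[!is.finite(t)] <- 0
  stats::setNames(t, names(e))
}

#' Expected number of studentised residuals beyond a Normal threshold
#'
#' Under the standard-Normal null, the expected count of \eqn{|t| >}
#' threshold among n probe sets is \eqn{2 n (1 - \Phi(threshold))}. For the
#' 22543 loci of a whole-genome array and the conventional threshold 3.5
#' this rounds to 10, with the two-sided band covering 99.95% of probe
#' sets; observing far more exceedances than this is the evidence that a
#' protocol systematically mis-amplifies specific loci.
#'
#' @param n number of loci.
#' @param threshold positive studentised-residual cutoff.
#' @return list with \code{expected} (exact), \code{rounded} (nearest
#'   integer) and \code{coveragePct} (two-sided coverage, percent).
#' @examples
#' expectedExceedances(22543, 3.5)$rounded  # 10
#' @export
expectedExceedances <- function(n, threshold = 3.5) {
  stopifnot(n >= 1, threshold >= 0)
  expected <- n * 2 * (1 - stats::pnorm(threshold))
  list(expected = expected,
       rounded = round(expected),
       coveragePct = 100 * (2 * stats::pnorm(threshold) - 1))
}

#' Classify probe sets of one fit as over-/under-amplified
#'
#' Strict inequalities: studentised residual > threshold is over-amplified,
#' < -threshold under-amplified, anything else (including exactly the
#' threshold) is no call.
#'
#' @param fit a \linkS4class{PairwiseFit}.
#' @param threshold positive cutoff (default 3.5).
#' @return named character vector in \code{c("over", "under", "none")}.
#' @export
classifyFit <- function(fit, threshold = 3.5) {
  stopifnot(is(fit, "PairwiseFit"), threshold > 0)
  t <- fit@studentized
  cls <- rep("none", length(t))
  cls[t > threshold] <- "over"
  cls[t < -threshold] <- "under"
  stats::setNames(cls, names(t))
}

## Matched array pairs of (reference, test) protocols for every (tissue,
## replicate); returns a data.frame of column indices.
.matchedPairs <- function(cd, reference, test) {
  keys <- paste(cd$tissue, cd$replicate)
  refIdx <- which(cd$protocol == reference)
  testIdx <- which(cd$protocol == test)
  m <- match(keys[refIdx], keys[testIdx])
  if (any(is.na(m)))
    stop(sprintf("no matched %s array for every %s array", test, reference))
  data.frame(ref = refIdx, test = testIdx[m],
             tissue = cd$tissue[refIdx],
             replicate = cd$replicate[refIdx])
}

#' Call mis-amplified probe sets from a protocol-comparison experiment
#'
#' The full classifier: for each comparison (by default one-cycle vs
#' two-cycle and IVT-Express vs two-cycle), each tissue and each replicate,
#' the two-cycle log2 expression is regressed on the reference protocol's,
#' probe sets with externally studentised residual beyond \code{threshold}
#' are classed over-/under-amplified, calls from the tissues of one
#' (comparison, replicate) are pooled, and a probe set reaches the
#' consensus mis-amplified list when it is called in the same direction in
#' at least \code{minReplicates} replicates within each comparison
#' (strict reading; \code{strict = FALSE} relaxes the quorum to the pooled
#' comparisons with at least one call in each).
#'
#' @param expr an \linkS4class{ExpressionMatrix} whose \code{colData}
#'   carries tissue, protocol and replicate.
#' @param threshold studentised-residual cutoff (default 3.5).
#' @param comparisons list of \code{c(reference, test)} protocol pairs.
#' @param minReplicates replicate quorum for consensus (default 2).
#' @param strict quorum reading; see Details in [consensusCalls()].
#' @return an \linkS4class{AmplificationCallSet}.
#' @examples
#' sim <- simulateProbeData(SimConfig(nProbeSets = 200, nOver = 3,
#'                                    nUnder = 3, seed = 11))
#' calls <- callAmplification(rmaSummarize(sim$probes))
#' consensusOver(calls)
#' @export
callAmplification <- function(expr, threshold = 3.5,
                              comparisons = list(
                                c("one_cycle", "two_cycle"),
                                c("ivt_e", "two_cycle")),
                              minReplicates = 2L, strict = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"), threshold > 0)
  cd <- colData(expr)
  m <- assay(expr, "exprs")
  fits <- list()
  rows <- list()
  for (cmp in comparisons) {
    label <- paste(cmp[1], "vs", cmp[2])
    pairs <- .matchedPairs(cd, cmp[1], cmp[2])
    for (i in seq_len(nrow(pairs))) {
      fit <- fitPairwise(m[, pairs$ref[i]], m[, pairs$test[i]],
                         reference = cmp[1], test = cmp[2],
                         tissue = pairs$tissue[i],
                         replicate = pairs$replicate[i])
      fits[[length(fits) + 1L]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        probeSetId = rownames(m),
        comparison = label,
        tissue = pairs$tissue[i],
        replicate = as.integer(pairs$replicate[i]),
        studentized = unname(fit@studentized),
        class = unname(classifyFit(fit, threshold)),
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  cs <- new("AmplificationCallSet", calls = calls, fits = fits,
            threshold = threshold, minReplicates = as.integer(minReplicates),
            strict = strict, consensusOver = character(0),
            consensusUnder = character(0), discordant = character(0))
  consensusCalls(cs, minReplicates = minReplicates, strict = strict)
}

## Per (comparison, replicate) pooled direction of one probe set's calls
## across tissues: over/under if any tissue called it and no tissue called
## the opposite; conflicting tissues yield NA (discordant, no call).
.pooledCalls <- function(calls) {
  key <- paste(calls$probeSetId, calls$comparison, calls$replicate,
               sep = "\t")
  key <- factor(key, levels = unique(key))
  hasOver <- tapply(calls$class == "over", key, any)
  hasUnder <- tapply(calls$class == "under", key, any)
  dir <- ifelse(hasOver & !hasUnder, "over",
                ifelse(hasUnder & !hasOver, "under",
                       ifelse(hasOver & hasUnder, "conflict", "none")))
  parts <- do.call(rbind, strsplit(names(dir), "\t", fixed = TRUE))
  data.frame(probeSetId = parts[, 1], comparison = parts[, 2],
             replicate = as.integer(parts[, 3]), dir = unname(dir),
             stringsAsFactors = FALSE)
}

#' Recompute the consensus mis-amplified lists of a call set
#'
#' A probe set enters \code{consensusOver} when, in each of the two
#' comparisons against the two-cycle protocol, it is called over-amplified
#' in at least \code{minReplicates} of the replicates (tissues pooled);
#' symmetrically for \code{consensusUnder}. A probe set called over in one
#' comparison and under in the other (or in conflicting directions across
#' tissues of one replicate) is excluded from both lists and recorded as
#' discordant. With \code{strict = FALSE} the quorum instead applies to the
#' calls pooled over both comparisons, requiring at least one supporting
#' replicate in each comparison.
#'
#' @param callset an \linkS4class{AmplificationCallSet}.
#' @param minReplicates replicate quorum (default 2).
#' @param strict quorum reading (default TRUE, per-comparison).
#' @return the call set with consensus slots filled.
#' @export
consensusCalls <- function(callset, minReplicates = 2L, strict = TRUE) {
  stopifnot(is(callset, "AmplificationCallSet"))
  pooled <- .pooledCalls(callset@calls)
  comparisons <- unique(callset@calls$comparison)
  active <- pooled[pooled$dir %in% c("over", "under", "conflict"), ]
  conflictGenes <- unique(active$probeSetId[active$dir == "conflict"])
  ## a gene called over somewhere and under elsewhere (across replicates or
  ## comparisons) has no coherent direction: excluded from both lists
  bothDirs <- intersect(active$probeSetId[active$dir == "over"],
                        active$probeSetId[active$dir == "under"])
  discordant <- union(conflictGenes, bothDirs)
  active <- active[!active$probeSetId %in% discordant, ]
  consensus <- list(over = character(0), under = character(0))
  for (direction in c("over", "under")) {
    hits <- active[active$dir == direction, ]
    if (!nrow(hits)) next
    perCmp <- table(factor(hits$probeSetId),
                    factor(hits$comparison, levels = comparisons))
    if (strict) {
      ok <- rownames(perCmp)[apply(perCmp >= minReplicates, 1, all)]
    } else {
      ok <- rownames(perCmp)[rowSums(perCmp) >= minReplicates &
                               apply(perCmp >= 1L, 1, all)]
    }
    consensus[[direction]] <- sort(ok)
  }
  both <- intersect(consensus$over, consensus$under)
  if (length(both)) {
    discordant <- union(discordant, both)
    consensus$over <- setdiff(consensus$over, both)
    consensus$under <- setdiff(consensus$under, both)
  }
  if (length(discordant))
    message(length(discordant),
            " probe set(s) excluded for discordant directions")
  callset@minReplicates <- as.integer(minReplicates)
  callset@strict <- strict
  callset@consensusOver <- setdiff(consensus$over, discordant)
  callset@consensusUnder <- setdiff(consensus$under, discordant)
  callset@discordant <- sort(discordant)
  validObject(callset)
  callset
}

#' Per-fit over/under call counts
#'
#' Summary of the number of over- and under-amplified calls in every
#' (comparison, tissue, replicate) fit, alongside the count expected under
#' the Normal null — the per-fit tabulation used to show that observed
#' exceedances far outnumber chance.
#'
#' @param callset an \linkS4class{AmplificationCallSet}.
#' @return data.frame with one row per fit: comparison, tissue, replicate,
#'   nOver, nUnder, n, expectedNull.
#' @export
callCounts <- function(callset) {
  stopifnot(is(callset, "AmplificationCallSet"))
  calls <- callset@calls
  key <- interaction(calls$comparison, calls$tissue, calls$replicate,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(calls, key), function(d) {
    data.frame(comparison = d$comparison[1], tissue = d$tissue[1],
               replicate = d$replicate[1],
               nOver = sum(d$class == "over"),
               nUnder = sum(d$class == "under"),
               n = nrow(d),
               expectedNull = expectedExceedances(nrow(d),
                                                 callset@threshold)$expected,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$comparison, out$tissue, out$replicate), ]
}
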