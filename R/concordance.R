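#' Squared Pearson correlation of two log2 expression vectors
#'
#' The replicate/protocol agreement measure: R-squared of matched log2
#' expression. Symmetric in its arguments and invariant under affine
#' transformation of either.
#'
#' @param a,b numeric vectors of equal length (>= 3), matched gene order,
#'   each with non-zero variance.
#' @return R-squared in [0, 1].
#' @examples
#' x <- rnorm(100)
#' pairwiseR2(x, 2 * x + 1)  # 1
#' @export
pairwiseR2 <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("at least 3 matched genes are required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: an input has zero variance")
  stats::cor(a, b)^2
}

#' R-squared matrix over all array pairs
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @return symmetric matrix of pairwise R-squared values (unit diagonal).
#' @export
pairwiseR2Matrix <- function(expr) {
  stopifnot(is(expr, "ExpressionMatrix"))
  stats::cor(assay(expr, "exprs"))^2
}

#' Principal component scores of the arrays
#'
#' Gene-centered (uncentered in arrays, unscaled) singular value
#' decomposition of the log2 expression matrix: each array receives
#' coordinates on the leading components, with the fraction of variance
#' each component explains. In a two-tissue, three-protocol labelling
#' comparison the leading component separates the tissues and the second
#' the two-cycle arrays from the rest.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with >= 2 arrays.
#' @param nComponents number of components to return.
#' @return list with \code{scores} (arrays x components) and
#'   \code{explained} (variance fractions, non-increasing, summing to <= 1).
#' @examples
#' sim <- simulateProbeData(SimConfig(nProbeSets = 100, seed = 4))
#' pcaScores(rmaSummarize(sim$probes))$explained
#' @export
pcaScores <- function(expr, nComponents = 2L) {
  stopifnot(is(expr, "ExpressionMatrix"))
  m <- assay(expr, "exprs")
  if (ncol(m) < 2L) stop("PCA requires at least 2 arrays")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = explained[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Median-normalize one array's natural-scale expression
#'
#' Divides each gene's expression by the array's median so arrays from
#' different experiments, scanners and labs become comparable: the output
#' median is exactly 1, and global rescaling of the array leaves the result
#' unchanged.
#'
#' @param x positive numeric vector (one array, natural scale) or a matrix
#'   with arrays in columns.
#' @return relative expression with per-array median 1.
#' @examples
#' medianNormalize(c(1, 2, 3))
#' @export
medianNormalize <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, medianNormalize))
  if (!length(x)) stop("empty expression vector")
  if (any(x <= 0)) stop("expression values must be positive")
  med <- stats::median(x)
  if (med <= 0) stop("non-positive array median")
  x / med
}

#' Mean fold difference of a gene set between two array groups
#'
#' For each gene, the fold is its mean median-normalized expression across
#' the arrays of group A divided by its mean across group B; the summary is
#' the arithmetic mean of per-gene folds with standard error
#' SD / sqrt(n genes) — the form in which cross-experiment enrichment of
#' over-amplified gene sets is reported (for example "19.7 fold higher in
#' the two-cycle data"). Genes absent from either group are excluded with a
#' message. A log2-scale alternative (geometric mean fold) is available.
#'
#' @param geneSet character vector of gene ids.
#' @param groupA,groupB matrices of relative (median-normalized,
#'   natural-scale) expression, genes in rows, arrays in columns.
#' @param logScale if TRUE, average the per-gene log2 folds and return the
#'   antilogged geometric mean (SE on the log2 scale).
#' @return list with \code{fold} (mean fold), \code{se} (NA for a single
#'   gene), \code{n} genes used, and \code{perGene} folds.
#' @examples
#' a <- matrix(2, 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
#' b <- matrix(1, 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
#' foldSummary(c("g1", "g2", "g3"), a, b)$fold  # 2
#' @export
foldSummary <- function(geneSet, groupA, groupB, logScale = FALSE) {
  if (!length(geneSet)) stop("geneSet must be non-empty")
  present <- geneSet[geneSet %in% rownames(groupA) &
                       geneSet %in% rownames(groupB)]
  dropped <- setdiff(geneSet, present)
  if (length(dropped))
    message(length(dropped), " gene(s) absent from a group, excluded")
  if (!length(present)) stop("no genes of geneSet present in both groups")
  aMean <- rowMeans(groupA[present, , drop = FALSE])
  bMean <- rowMeans(groupB[present, , drop = FALSE])
  folds <- aMean / bMean
  n <- length(folds)
  if (logScale) {
    lf <- log2(folds)
    list(fold = 2^mean(lf),
         se = if (n > 1) stats::sd(lf) / sqrt(n) else NA_real_,
         n = n, perGene = folds)
  } else {
    list(fold = mean(folds),
         se = if (n > 1) stats::sd(folds) / sqrt(n) else NA_real_,
         n = n, perGene = folds)
  }
}
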