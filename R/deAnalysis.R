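#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending, the adjusted
#' value at rank i is the running minimum over j >= i of min(1, p_(j) m/j),
#' returned in the input order. Flagging genes with adjusted p at or below
#' a level controls the expected false-discovery proportion at that level.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, elementwise >= the raw values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two tissue groups
#'
#' Per-gene Welch two-sample t-test on log2 expression (equal-variance
#' pooled t optional), Benjamini-Hochberg adjustment, and the compound
#' filter: a gene is differentially expressed when its fold change exceeds
#' \code{fcThreshold} (strictly, on the natural scale) and its adjusted
#' p-value is at most \code{fdrLevel}. The log2 fold change is
#' mean(group A) - mean(group B) of log2 values, i.e. the log ratio of
#' geometric means. Genes with zero variance in both groups are handled as
#' a degenerate case: p is 0 when the group means differ and 1 when equal,
#' with a message.
#'
#' @param groupA,groupB matrices of log2 expression, genes in rows and
#'   replicate arrays in columns (>= 2 per group), identical row order.
#' @param fcThreshold natural-scale fold-change cutoff (default 2).
#' @param fdrLevel BH FDR level (default 0.05).
#' @param varEqual use the pooled-variance t-test instead of Welch.
#' @return data.frame with columns gene, log2FC, p, adjP, de (logical).
#' @examples
#' a <- matrix(rnorm(30, 5), 10, 3,
#'             dimnames = list(paste0("g", 1:10), NULL))
#' callDE(a, a + 0.01)$de
#' @export
callDE <- function(groupA, groupB, fcThreshold = 2, fdrLevel = 0.05,
                   varEqual = FALSE) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            nrow(groupA) == nrow(groupB),
            ncol(groupA) >= 2L, ncol(groupB) >= 2L)
  nA <- ncol(groupA); nB <- ncol(groupB)
  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  vA <- apply(groupA, 1, stats::var); vB <- apply(groupB, 1, stats::var)
  lfc <- mA - mB
  if (varEqual) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(se))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  p <- 2 * stats::pt(abs(lfc) / se, df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(lfc[degenerate] != 0, 0, 1)
    message(sum(degenerate),
            " gene(s) with zero within-group variance; p set by mean",
            " equality")
  }
  adjP <- bhAdjust(p)
  de <- abs(lfc) > log2(fcThreshold) & adjP <= fdrLevel
  data.frame(gene = rownames(groupA), log2FC = lfc, p = p, adjP = adjP,
             de = de, row.names = NULL, stringsAsFactors = FALSE)
}

#' DE calls per protocol between the two tissues of an experiment
#'
#' Runs [callDE()] separately on each protocol's arrays, contrasting the
#' two tissue groups, and returns the per-protocol DE gene sets.
#'
#' @param expr an \linkS4class{ExpressionMatrix} with tissue/protocol/
#'   replicate metadata (exactly two tissues).
#' @param fcThreshold,fdrLevel,varEqual passed to [callDE()].
#' @return named list: per protocol, the [callDE()] table plus a
#'   \code{deGenes} attribute-free character vector in element
#'   \code{genes}.
#' @export
deByProtocol <- function(expr, fcThreshold = 2, fdrLevel = 0.05,
                         varEqual = FALSE) {
  stopifnot(is(expr, "ExpressionMatrix"))
  cd <- colData(expr)
  tissues <- unique(cd$tissue)
  if (length(tissues) != 2L)
    stop("tissue contrast requires exactly two tissues")
  m <- assay(expr, "exprs")
  out <- list()
  for (k in unique(cd$protocol)) {
    a <- m[, cd$protocol == k & cd$tissue == tissues[1], drop = FALSE]
    b <- m[, cd$protocol == k & cd$tissue == tissues[2], drop = FALSE]
    tab <- callDE(a, b, fcThreshold, fdrLevel, varEqual)
    out[[k]] <- list(table = tab, genes = tab$gene[tab$de])
  }
  out
}

#' Three-set Venn region counts for per-protocol DE gene lists
#'
#' All seven region counts of the three-way Venn, plus the size of the
#' triple intersection as a rounded percentage of each protocol's DE list —
#' the overlap summary used to quantify how much the labelling protocol
#' shifts a differential-expression result.
#'
#' @param deSets named list of exactly three character vectors.
#' @return list with \code{sizes} (per-set), \code{regions} (the seven
#'   disjoint region counts, names like "A", "AB", "ABC"), \code{triple}
#'   and \code{triplePct} (rounded percent of each set).
#' @examples
#' vennCounts3(list(a = letters[1:4], b = letters[2:5], c = letters[3:6]))
#' @export
vennCounts3 <- function(deSets) {
  if (length(deSets) != 3L || is.null(names(deSets)))
    stop("deSets must be a named list of three gene sets")
  s <- lapply(deSets, unique)
  nm <- names(s)
  inA <- function(g, i) g %in% s[[i]]
  univ <- unique(unlist(s))
  member <- cbind(inA(univ, 1), inA(univ, 2), inA(univ, 3))
  pattern <- apply(member, 1, function(r) paste(which(r), collapse = ""))
  lab <- c("1" = "A", "2" = "B", "3" = "C", "12" = "AB", "13" = "AC",
           "23" = "BC", "123" = "ABC")
  regions <- stats::setNames(integer(7), unname(lab))
  tab <- table(pattern)
  regions[lab[names(tab)]] <- as.integer(tab)
  triple <- regions[["ABC"]]
  sizes <- vapply(s, length, integer(1))
  list(sizes = sizes, regions = regions, triple = triple,
       triplePct = stats::setNames(round(100 * triple / sizes), nm))
}
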