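# Independent oracles, deliberately naive and separate from the package
# implementation paths they check.

# Externally studentised residuals by literal delete-one refitting: for each
# observation, refit OLS without it, predict the held-out point, and scale
# the prediction error by its standard error under the refit.
deleteOneStudentized <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    xi <- x[-i]; yi <- y[-i]
    f <- stats::lm(yi ~ xi)
    s <- summary(f)$sigma
    xbar <- mean(xi)
    sxx <- sum((xi - xbar)^2)
    pred <- stats::coef(f)[1] + stats::coef(f)[2] * x[i]
    sePred <- s * sqrt(1 + 1 / (n - 1) + (x[i] - xbar)^2 / sxx)
    (y[i] - pred) / sePred
  }, numeric(1))
}

# Literal Benjamini-Hochberg step-up on sorted p-values.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive alternating row/column median sweeps for an additive two-way fit.
mpOracle <- function(z, maxIter = 50L, tol = 1e-9) {
  overall <- 0
  row <- numeric(nrow(z)); col <- numeric(ncol(z))
  r <- z
  for (it in seq_len(maxIter)) {
    rm <- apply(r, 1, median)
    row <- row + rm
    r <- r - rm
    cm <- median(row)
    overall <- overall + cm
    row <- row - cm
    cm <- apply(r, 2, median)
    col <- col + cm
    r <- sweep(r, 2, cm)
    rm <- median(col)
    overall <- overall + rm
    col <- col - rm
    if (max(abs(apply(r, 1, median))) < tol &&
        max(abs(apply(r, 2, median))) < tol) break
  }
  list(overall = overall, row = row, col = col, residuals = r)
}

# Tiny dense ProbeLevelSet built directly from a probe x array matrix of
# log2 values for a single probe-set layout.
makeProbeSet <- function(log2mat, nPos, genes, arrays = NULL) {
  nG <- length(genes)
  stopifnot(nrow(log2mat) == nG * nPos)
  if (is.null(arrays))
    arrays <- data.frame(tissue = "MS", protocol = "one_cycle",
                         replicate = seq_len(ncol(log2mat)))
  ids <- paste0("a", seq_len(ncol(log2mat)))
  m <- 2^log2mat
  dimnames(m) <- list(paste(rep(genes, each = nPos),
                            rep(seq_len(nPos), nG), sep = "_p"), ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(
      probeSetId = rep(genes, each = nPos),
      probePosition = rep(seq_len(nPos), nG),
      row.names = rownames(m)),
    colData = S4Vectors::DataFrame(
      tissue = arrays$tissue, protocol = arrays$protocol,
      replicate = as.integer(arrays$replicate), row.names = ids))
  new("ProbeLevelSet", se)
}

# Cached run of the default study-design simulation + pipeline so several
# test files can score the same seeded experiment without recomputing it.
.runCache <- new.env(parent = emptyenv())
defaultRun <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.runCache[[key]]))
    .runCache[[key]] <- runPipeline(SimConfig(seed = seed))
  .runCache[[key]]
}
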