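test_that("OLS fit recovers exact linear relations and matches lm", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  f <- fitPairwise(x, 2 * x + 1)
  expect_equal(f@slope, 2)
  expect_equal(f@intercept, 1)
  expect_equal(max(abs(f@residuals)), 0)
  set.seed(31)
  x2 <- rnorm(40); y2 <- 1.1 * x2 + rnorm(40, sd = 0.3)
  f2 <- fitPairwise(x2, y2)
  ref <- lm(y2 ~ x2)
  expect_equal(f2@slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(f2@intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(unname(f2@residuals), unname(residuals(ref)),
               tolerance = 1e-12)
  expect_error(fitPairwise(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("permuting loci permutes residuals identically", {
  set.seed(32)
  x <- rnorm(25); y <- x + rnorm(25, sd = 0.2)
  names(x) <- names(y) <- paste0("g", 1:25)
  f <- fitPairwise(x, y)
  perm <- sample(25)
  fp <- fitPairwise(x[perm], y[perm])
  expect_equal(fp@residuals, f@residuals[perm], tolerance = 1e-12)
  expect_equal(studentized(fp), studentized(f)[perm], tolerance = 1e-12)
})

test_that("studentised residuals match the delete-one oracle and rstudent", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    x <- rnorm(n)
    y <- 0.8 * x + rnorm(n, sd = 0.5)
    if (i %% 3 == 0) y[1] <- y[1] + 5  # planted outlier
    f <- fitPairwise(x, y)
    expect_equal(unname(studentized(f)), deleteOneStudentized(x, y),
                 tolerance = 1e-9)
    expect_equal(unname(studentized(f)), unname(rstudent(lm(y ~ x))),
                 tolerance = 1e-9)
  }
})

test_that("exact fits studentise to all zeros with a message", {
  x <- 1:10
  expect_message(f <- fitPairwise(x, 3 * x - 2), "exact fit")
  expect_equal(unname(studentized(f)), rep(0, 10))
})

test_that("null exceedance fraction matches the Normal tail at large n", {
  set.seed(34)
  n <- 22543
  x <- rnorm(n, 8, 2); y <- x + rnorm(n, sd = 0.4)
  f <- fitPairwise(x, y)
  pNull <- 2 * (1 - pnorm(3.5))
  observed <- mean(abs(studentized(f)) > 3.5)
  se <- sqrt(pNull * (1 - pNull) / n)
  expect_lt(abs(observed - pNull), 3 * se + 1e-12)
})

test_that("expected exceedance arithmetic is exact", {
  ee <- expectedExceedances(22543, 3.5)
  expect_equal(ee$rounded, 10)
  expect_equal(round(ee$coveragePct, 2), 99.95)
  expect_equal(expectedExceedances(1000, 0)$expected, 1000)
  expect_lt(expectedExceedances(1e6, 10)$expected, 1e-4)
})

test_that("classification uses strict threshold inequalities", {
  f <- new("PairwiseFit", reference = "one_cycle", test = "two_cycle",
           tissue = "MS", replicate = 1L, slope = 1, intercept = 0,
           residuals = setNames(numeric(4), paste0("g", 1:4)),
           studentized = setNames(c(3.6, -3.6, 3.5, -3.5),
                                  paste0("g", 1:4)),
           n = 4L)
  cls <- classifyFit(f, threshold = 3.5)
  expect_equal(unname(cls), c("over", "under", "none", "none"))
})

test_that("consensus rule enforces quorum within each comparison", {
  mkCalls <- function(spec) {
    # spec: list of (gene, comparison, replicate, class)
    base <- expand.grid(probeSetId = "g1",
                        comparison = c("one_cycle vs two_cycle",
                                       "ivt_e vs two_cycle"),
                        tissue = "MS", replicate = 1:3,
                        stringsAsFactors = FALSE)
    base$studentized <- 0; base$class <- "none"
    for (s in spec) {
      i <- base$comparison == s[[2]] & base$replicate == s[[3]]
      base$class[i] <- s[[4]]
      base$studentized[i] <- if (s[[4]] == "over") 4 else -4
    }
    new("AmplificationCallSet", calls = base, fits = list(),
        threshold = 3.5, minReplicates = 2L, strict = TRUE,
        consensusOver = character(0), consensusUnder = character(0),
        discordant = character(0))
  }
  cmp1 <- "one_cycle vs two_cycle"; cmp2 <- "ivt_e vs two_cycle"
  # over in reps {1,2} of cmp1 and {1,3} of cmp2 -> consensus over
  cs <- consensusCalls(mkCalls(list(
    list("g1", cmp1, 1, "over"), list("g1", cmp1, 2, "over"),
    list("g1", cmp2, 1, "over"), list("g1", cmp2, 3, "over"))))
  expect_equal(consensusOver(cs), "g1")
  # over only in cmp1 -> excluded (fails the both-lists clause)
  cs2 <- consensusCalls(mkCalls(list(
    list("g1", cmp1, 1, "over"), list("g1", cmp1, 2, "over"))))
  expect_length(consensusOver(cs2), 0)
  # one replicate in each comparison -> excluded under strict reading
  spec1each <- list(list("g1", cmp1, 1, "over"), list("g1", cmp2, 2, "over"))
  cs3 <- consensusCalls(mkCalls(spec1each))
  expect_length(consensusOver(cs3), 0)
  # ... but admitted under the pooled reading (>=2 overall, >=1 each list)
  cs4 <- consensusCalls(mkCalls(spec1each), strict = FALSE)
  expect_equal(consensusOver(cs4), "g1")
  # opposite directions across comparisons -> discordant, in neither list
  cs5 <- suppressMessages(consensusCalls(mkCalls(list(
    list("g1", cmp1, 1, "over"), list("g1", cmp1, 2, "over"),
    list("g1", cmp2, 1, "under"), list("g1", cmp2, 2, "under")))))
  expect_length(consensusOver(cs5), 0)
  expect_length(consensusUnder(cs5), 0)
  expect_equal(cs5@discordant, "g1")
})

test_that("null calibration: shift-free data shows only chance exceedances", {
  cfg <- SimConfig(nProbeSets = 2000, nOver = 0, nUnder = 0, seed = 101)
  sim <- simulateProbeData(cfg)
  res <- runPipeline(probes = sim$probes, truth = sim$truth)
  lambda <- expectedExceedances(2000, 3.5)$expected
  lo <- qpois(0.005, lambda); hi <- qpois(0.995, lambda)
  counts <- res$callCounts$nOver + res$callCounts$nUnder
  expect_true(all(counts >= lo & counts <= hi))
  expect_length(consensusOver(res$calls), 0)
  expect_length(consensusUnder(res$calls), 0)
})

test_that("planted mis-amplified genes are recovered with correct signs", {
  res <- defaultRun()
  truth <- res$truth
  over <- plantedGenes(truth)$over
  under <- plantedGenes(truth)$under
  rec <- res$summary$recovery
  expect_gte(rec$recoveryRate, 0.9)
  expect_equal(rec$signErrors, 0)
  # direction consistency: no planted over gene in the under list
  expect_length(intersect(over, consensusUnder(res$calls)), 0)
  expect_length(intersect(under, consensusOver(res$calls)), 0)
  # false positives within the Poisson 99% bound on chance consensus
  lambda <- expectedExceedances(2000, 3.5)$expected
  expect_lte(rec$falsePositives, qpois(0.995, lambda))
})

test_that("raising the threshold never enlarges any call set", {
  set.seed(35)
  x <- rnorm(500, 8, 2); y <- x + rnorm(500, sd = 0.3)
  y[1:5] <- y[1:5] + 4
  names(x) <- names(y) <- sprintf("g%03d", 1:500)
  f <- fitPairwise(x, y)
  for (thr in c(2, 2.5, 3, 3.5)) {
    loose <- classifyFit(f, thr)
    tight <- classifyFit(f, thr + 0.5)
    expect_true(all(names(tight)[tight == "over"] %in%
                      names(loose)[loose == "over"]))
    expect_true(all(names(tight)[tight == "under"] %in%
                      names(loose)[loose == "under"]))
  }
})
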