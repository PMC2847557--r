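---
title: "Detecting probe sets mis-represented by two-cycle RNA amplification"
author: "ampliBias"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Detecting probe sets mis-represented by two-cycle RNA amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliBias)
```

## The problem

Profiling small samples — dissected tissue zones, sorted cell populations —
on 3'-biased short-oligonucleotide expression arrays requires RNA
amplification. The standard one-cycle labelling protocol needs about a
microgram of total RNA; small-sample protocols either amplify twice
(two-cycle labelling, with a second round of in vitro transcription) or use
a more efficient single-round chemistry (IVT-Express). Each extra
amplification round starts reverse transcription from the transcript's 3'
end, so incomplete synthesis depresses signal at 5'-proximal probes, and
some transcripts are reproducibly over- or under-represented after the
second round. Calling such probe sets, so that downstream analyses can
treat them with caution, is what this package does.

The experimental design the package targets is a matched protocol
comparison: the same biological replicates (here two root tissue zones,
meristem `MS` and elongation zone `EZ`, in three biological replicates)
labelled with each of the three protocols and hybridised to the same array
type, giving 18 arrays. The probe sets of the emulated array carry 11
perfect-match probes numbered 1 (5'-most) to 11 (3'-most).

## Preprocessing

Probe-level intensities are log2-transformed, quantile-normalized across
arrays (every array is forced onto the common reference distribution given
by the mean of per-rank order statistics; ties within an array receive the
mean of the reference values at their tied ranks), and summarized per probe
set by Tukey median polish of the probes × arrays block: alternating
row/column median sweeps fit `overall + probe + array` robustly, and the
probe-set expression on an array is `overall + array effect` with probe
effects recentred to median zero. These are the between-array and
summarization steps of the RMA pipeline. RMA's convolution
(Normal + exponential) background correction is deliberately not applied:
the simulator produces no optical background, none of the downstream
statistics (a within-probe-set contrast, regression residuals, fold
ratios) depends on an additive background estimate, and omitting it keeps
the preprocessing exactly invertible on noise-free inputs, which the test
suite exploits. `rmaSummarize()` documents this as a deviation from
literal RMA.

Median-polish defaults are `maxIter = 10` sweeps and `tol = 0.01` log2
units on the row/column residual medians — conventional RMA-style
settings; both are arguments. The median of an even number of values is
the mean of the two central order statistics throughout, which makes the
worked examples in the tests exact.

## The 5'/3' bias statistic

For each probe set on each array, the bias is

    median(log2 signal, probes 1-5) - median(log2 signal, probes 7-11)

with probe 6 unused; positive values indicate 5' bias, negative values 3'
bias. Because it is a within-probe-set contrast, adding any constant to an
array leaves it unchanged, and reversing the probe order negates it
exactly — both are tested properties. For probe counts other than 11 the
blocks generalize to the first and last `floor((n-1)/2)` positions.

Per-protocol summaries are the pooled mean over all (probe set, array)
bias values in the group, and trimmed quantile curves restricted to
probabilities in [0.05, 0.95] (the extreme biases are very large;
trimming keeps the curves readable). Quantiles interpolate linearly
between order statistics (type 7). Two choices here were genuinely open:
whether to compute biases before or after quantile normalization (the
pipeline default is after, for between-array comparability; the
`normalize` flag of `rmaSummarize()` and direct use of
`probePositionBias()` on un-normalized data expose the alternative), and
whether protocol means pool gene×array values or average per-array means
first (we pool; with balanced designs and equal probe-set counts per array
the two agree).

## The mis-amplification classifier

For each comparison (one-cycle vs two-cycle, IVT-E vs two-cycle), each
tissue and each replicate, the two-cycle array's log2 expression is
regressed on the matched reference array's by ordinary least squares, with
the two-cycle sample as the response, so a positive residual means "higher
in two-cycle than the trend predicts" — over-amplified. Residuals are
externally studentised: \(t_i = e_i / (s_{(i)} \sqrt{1 - h_{ii}})\) with
the hat diagonal \(h_{ii}\) and the leave-one-out residual scale
\(s_{(i)}\). Under the null they follow a t distribution on \(n - 3\)
degrees of freedom, indistinguishable from a standard Normal at
whole-array \(n\); at threshold 3.5 the band covers 99.95% of probe sets
and only about 10 of 22543 loci would exceed it by chance
(`expectedExceedances(22543, 3.5)`). Inequalities are strict: \(|t|\)
exactly 3.5 is no call. An exact fit (all residuals zero) defines all
studentised residuals as zero, with a message.

A probe set is consensus mis-amplified when it is called in the same
direction in at least two of the three replicates *within each* of the two
comparisons. That quantifier placement is the strict reading of an
ambiguous rule; the laxer pooled reading (at least two supporting
replicates overall, with at least one in each comparison) is available via
`strict = FALSE` in `consensusCalls()`. Tissues are fitted separately —
six fits per comparison, mirroring a per-tissue tabulation — and a gene
counts as called in a (comparison, replicate) if either tissue's fit calls
it; genes called in opposite directions anywhere are excluded from both
consensus lists and logged as discordant.

## Concordance and DE-list overlap

Replicate and protocol agreement is measured by squared Pearson
correlation of matched log2 expression and by gene-centered, unscaled PCA
of the arrays (standard for expression data; scaling per gene would
up-weight low-variance genes). For cross-experiment comparison, each
array's natural-scale expression is divided by its median
(`medianNormalize()`), and a gene set's enrichment between two array
groups is the arithmetic mean of per-gene folds with standard error
SD/√(genes) (`foldSummary()`; the arithmetic form matches how such fold
summaries are conventionally reported, and a geometric/log2 option is
provided).

Differential expression between the two tissues is called per protocol by
a per-gene Welch t-test on log2 values (the test is an interpretation —
only the thresholds are canonical; an equal-variance option exists), with
Benjamini-Hochberg adjustment and the compound filter: natural-scale fold
change strictly greater than 2 and adjusted p at most 0.05. The three
protocols' DE lists are compared by three-set Venn region counts, with the
triple intersection reported as a rounded percentage of each list.

## The synthetic-data generator

`simulateProbeData()` draws, on the log2 scale,

    y = theta_g + tau_gt + phi_gp + delta_k * (p - 6)/5
        + s_g * [k = two_cycle] + noise

and exponentiates (floored at 1 so the log2 transform stays defined).
`theta` is the gene baseline, `tau` a gene×tissue effect, `phi` a
per-probe affinity, `delta_k` the protocol's linear 3' gradient across the
probe span, and `s_g` the planted signed shift of the mis-amplified genes,
applied only under two-cycle labelling. The defaults are the study
conditions the package is tested under: 2000 probe sets (a desk-scale
stand-in for a 22810-probe-set array; full size is one argument away),
baseline mean 8 and SD 2 log2 units (typical post-RMA expression spread),
affinity SD 0.7 (probe effects are routinely larger than replicate
noise), tissue-effect SD 1.0, gradients 0.25 / 1.2 / 0.4 for one-cycle /
two-cycle / IVT-E (all protocols somewhat 3'-biased, two-cycle markedly
the worst, IVT-E slightly worse than one-cycle), 20 over- and 20
under-amplified genes with |shift| uniform in [2, 6] log2 units, and
replicate noise SD 0.25. A linear gradient is the simplest monotone model
that produces left-shifted bias distributions; shifts apply uniformly
across a gene's probes because classification is at probe-set level. With
a pure gradient `delta`, no noise and no affinity scatter, every affected
probe set's bias is exactly `-1.2 * delta` — the closed form
`(median of positions 1-5 minus median of positions 7-11) of
delta*(p-6)/5` — which the tests assert.

What the generator does *not* emulate: optical background and scanner
saturation, spatial artifacts, mismatch probes, cross-hybridisation,
sequence-dependent (GC, secondary-structure) amplification failure — the
planted shifts are phenomenological, as no quantitative mechanism for why
specific loci mis-amplify is established. Passing recovery tests therefore
show that the statistical procedure detects shifts of the planted kind at
the design's noise level, not that it would enumerate every unreliable
probe set on a real array.

## Numerical choices and degenerate inputs

* Quantile normalization of a single array is the identity; ragged input
  is rejected.
* A probe set with a single probe skips the polish and passes through,
  with a message.
* Zero-variance reference vectors make the regression degenerate and
  raise an error rather than returning NaN slopes.
* A leave-one-out variance that cancels to a tiny negative number by
  floating-point round-off is clamped to zero; the corresponding exact
  outlier would have an infinite studentised residual and is mapped to 0
  only in the all-residuals-zero case.
* Genes with zero within-group variance in the DE test get p = 0 when the
  group means differ and p = 1 when equal, with a message.
* BH adjustment, PCA, the polish core and the Welch p-values are delegated
  to `stats::p.adjust`, `stats::prcomp`, `stats::medpolish` and `pt`;
  the studentisation, bias statistic, consensus logic and generator are
  implemented here and cross-checked in the tests against independent
  brute-force oracles (delete-one refits, literal step-up, alternating
  median sweeps).

## Problem sizes used in the tests

The test suite and the acceptance script run the full pipeline at 2000
probe sets × 11 probes × 18 arrays, which completes in seconds while
leaving the null calibration informative (expected ≈ 0.93 chance
exceedances per fit at threshold 3.5). Oracle-equivalence suites use
n ≤ 50 regressions and ≤ 1000 p-values, where brute force is exact and
fast. The replicate-noise convergence check uses 200 replicates of a
25-gene design.

## Known limitations

* The classifier assumes a globally linear cross-protocol relationship;
  lowess-style local trends or robust regression are not offered.
* Consensus calling needs the full two-comparison, three-replicate
  design; partial designs work for per-fit calls but not for the
  consensus lists.
* No probe-sequence analysis: the package flags *which* probe sets are
  mis-amplified, not *why*.
* Real-array identities of mis-amplified probe sets cannot be reproduced
  from simulation; applying the pipeline to deposited datasets requires
  exporting their probe-level data to the documented TSV schema first.
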