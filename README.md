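# ampliBias

Detection of probe sets mis-represented by two-cycle RNA amplification on
3'-biased short-oligonucleotide expression arrays.

## The problem

Small samples — dissected tissue zones, sorted cells — don't yield enough
RNA for standard one-cycle array labelling, so a second round of in vitro
transcription (two-cycle amplification) or a higher-efficiency single-round
kit (IVT-Express) is used instead. The extra round is not neutral: it
steepens the 3' signal bias that incomplete reverse transcription already
causes, and it reproducibly over- or under-represents a small set of
specific transcripts. `ampliBias` implements the statistical workflow that
detects those probe sets from a matched protocol-comparison experiment
(here: two tissues × three protocols × three biological replicates, probe
sets of 11 perfect-match probes numbered 1 = 5'-most to 11 = 3'-most), for
analysts who need to know which genes' two-cycle measurements to distrust.

## The statistics

* **Preprocessing** — log2, between-array quantile normalization, and
  Tukey median-polish summarization of each probe set's probes × arrays
  block (the RMA normalization and summarization steps; `rmaSummarize()`).
* **5'/3' bias statistic** — per probe set and array,
  `median(log2, probes 1–5) − median(log2, probes 7–11)`; positive = 5'
  bias, negative = 3' bias. Protocol means and trimmed ([0.05, 0.95])
  quantile curves compare protocols (`probePositionBias()`, `meanBias()`,
  `trimmedQuantileCurve()`).
* **Mis-amplification classifier** — per comparison (one-cycle vs
  two-cycle, IVT-E vs two-cycle), tissue and replicate, OLS of two-cycle
  log2 expression on the reference protocol's; externally studentised
  residuals *t<sub>i</sub> = e<sub>i</sub> / (s<sub>(i)</sub> √(1 −
  h<sub>ii</sub>))*; *t* > 3.5 ⇒ over-amplified, *t* < −3.5 ⇒
  under-amplified (±3.5 covers 99.95% of a standard Normal — about 10
  chance exceedances among 22543 loci). Consensus: same-direction calls in
  ≥ 2 of 3 replicates within *each* comparison (`callAmplification()`).
* **Concordance** — pairwise R² of log2 expression, gene-centered PCA of
  arrays, median-of-array relative expression and mean-fold ± SE
  summaries of gene sets between array groups.
* **DE-list overlap** — per-protocol Welch t + Benjamini–Hochberg FDR
  (fold change > 2, FDR ≤ 0.05) between tissues, with three-set Venn
  counts and triple-overlap percentages.

A seeded probe-level simulator (`simulateProbeData()`) generates data with
known tissue effects, probe affinities, protocol-specific linear 3'
gradients and planted two-cycle shifts, so every stage is verifiable
against ground truth without downloading arrays.

## Worked example

```r
library(ampliBias)

sim  <- simulateProbeData(SimConfig(seed = 42))   # 2000 probe sets, 18 arrays
expr <- rmaSummarize(sim$probes)

meanBias(probePositionBias(quantileNormalize(log2Transform(sim$probes))))
#>       group   meanBias     n
#> 1 one_cycle -0.3168633 12000
#> 2 two_cycle -1.3916652 12000
#> 3     ivt_e -0.5004517 12000

calls <- callAmplification(expr)
calls
#> AmplificationCallSet: 12 fits, threshold 3.5
#>   consensus: 19 over-amplified, 20 under-amplified (>= 2 replicates per comparison, strict reading)

expectedExceedances(22543, 3.5)$rounded
#> [1] 10
```

The mean-bias table shows every protocol somewhat 3'-biased (negative) and
two-cycle markedly the worst — the diagnostic signature. The call set
recovers the planted mis-amplified genes: of 20 + 20 planted shifts, this
seed recovers 39 with 0 sign errors and 0 false positives
(`runPipeline(SimConfig(seed = 42))$summary$recovery`). The
`expectedExceedances` line is the null yardstick: among 22543 loci only
~10 would pass |t| > 3.5 by chance, so the ~40 per fit observed here (and
the ~100 per fit seen on real protocol comparisons) are systematic.

`runPipeline()` chains every stage and optionally writes all outputs
(probe/expression/bias TSVs, call tables, consensus gene lists, R² matrix,
DE tables) to a directory.

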