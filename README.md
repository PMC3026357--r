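# arrayConcord

Concordance analysis of differentially expressed gene (DEG) lists between
two-sample microarray experiments, in the MAQC style.

## The problem

When the same pair of RNA samples (A and B) is profiled in two experiments —
different platforms, different years, or arrays of different quality (for
example, arrays stored past their expiration date) — how well do the two
experiments agree on *which* genes are differentially expressed, and in which
direction? `arrayConcord` implements the analysis stack used to answer this
for Affymetrix-style probe-level data, for anyone assessing array quality,
reagent stability or cross-platform reproducibility.

## What it computes

**DEG selection (fold-change ranking with a non-stringent p filter).** Per
gene, Welch's t statistic on log2 expression,

    t = (mean_B − mean_A) / sqrt(s²_A/n_A + s²_B/n_B),

with Welch–Satterthwaite degrees of freedom and no multiple-testing
correction. Genes with p < 0.05 are ranked by log2 fold change and the top
*L* genes per regulation direction form a 2*L*-gene DEG list.

**POG — percentage of overlapping genes.** For two equal-size,
direction-split lists,

    POG = 100 · (DD + UU) / (2L),

where *DD* and *UU* count the genes commonly down- and up-regulated. POG is
swept over L = 1 … max shared L to give a POG curve; a pointwise mean of
several curves with a t-interval gives a reference band against which a new
comparison can be judged. Directional agreement is also reported on three
gene universes of increasing stringency: *all* common genes, genes with
p < 0.05 in *either* experiment, and in *both*.

**Summarization and QC.** Probe-level intensities are processed with
RMA-style background correction (normal + exponential convolution, mode-based
estimators), quantile normalization and log2 median-polish summarization.
Array quality is reported as the MAS5-style scaling factor (target / trimmed
mean; values far above 1 mean weak signal) and the Present-call percentage
from Wilcoxon signed-rank detection calls on PM/MM discrimination scores.

**Synthetic data with ground truth.** A seeded generator produces a paired
*reference*/*degraded* platform experiment — per-gene true log2 fold changes,
replicate noise, shared probe affinities, exponential additive background —
where the degraded platform has compressed fold changes, a downward intensity
shift, a narrower between-gene spread and inflated background. Every stage of
the pipeline is testable against this truth.

## Worked example

```r
library(arrayConcord)

cfg <- SimulationConfig(nGenes = 2000, seed = 42)
sim <- simulateExperimentPair(cfg)
sim$truth
#> GroundTruth: 2000 genes, 1389 DE (715 up, 674 down)

exprRef <- rmaSummarize(sim$reference)   # RMA per platform, as in practice
exprDeg <- rmaSummarize(sim$degraded)
degRef  <- welchTTest(exprRef)
degDeg  <- welchTTest(exprDeg)
degRef
#> DifferentialResult: 2000 genes, groups n_A=3 n_B=3
#>   p < 0.05: 1333 genes; |log2FC| range [0.000413, 8.97]

directionalAgreement(degDeg, degRef, "either")
#> Directional agreement [either]: 87.92% (1194 of 1358 genes)

pogCurve(degDeg, degRef, label = "degraded vs reference")
#> POGCurve 'degraded vs reference': 282 points, 2L in [2, 564]
#>   POG range [37.5, 76.1], final 67.6%

compressionSlope(degDeg, degRef)
#> [1] 0.5852015
```

Reading these numbers: of the 1,358 genes significant in at least one
platform, 87.9% change in the same direction on both; the top-ranked DEG
lists overlap between 37% and 76% depending on list size; and the degraded
platform's fold changes are compressed to ~0.59 of the reference's (a
through-origin regression slope below 1), the compound effect of the
generator's compression parameter and the low-intensity shrinkage of
background correction. Per-array QC shows the degradation signature —
scaling factor 0.74 → 3.17, Present calls 93.5% → 54.2%, mean log2 intensity
7.65 → 6.43, between-gene SD 2.56 → 1.66:

```r
qc <- rbind(arrayQC(sim$reference, exprRef), arrayQC(sim$degraded, exprDeg))
round(qc[c(1, 7), -1], 2)
#>   scaling_factor percent_present mean_log2 sd_log2
#> 1           0.74           93.50      7.65    2.56
#> 7           3.17           54.15      6.43    1.66
```

`runPipeline()` (or `inst/scripts/concord-pipeline.R` from a shell) chains
simulate → summarize → degs → pog → report from one YAML config, writing
TSVs with deterministic provenance headers.

## Limitations

The simulator reproduces the phenomenology of degraded arrays (compression,
signal loss, background inflation), not its chemistry; detection-call rates
depend strongly on the assumed background level. Joint quantile
normalization across the two samples distorts individual fold changes
whenever the samples' intensity distributions differ — see the methods
vignette (`vignettes/array-concordance-methods.Rmd`) for the full discussion
of model assumptions, parameter defaults and numerical choices.
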