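---
title: "Methods: DEG-list concordance between microarray experiments"
author: "arrayConcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DEG-list concordance between microarray experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayConcord)
```

# Scope and model

`arrayConcord` measures agreement between two two-sample (A vs B) microarray
experiments at the level of differentially-expressed-gene (DEG) *lists*. The
analysis chain is:

1. probe-level intensities → gene-level log2 expression (RMA-style
   summarization), per experiment;
2. per-gene Welch t statistics and log2 fold changes (B over A);
3. DEG selection by fold-change ranking after a non-stringent p filter;
4. concordance statistics: POG, POG-vs-list-size curves with a reference
   confidence band, and directional agreement under three scenarios.

Each step is deliberately the plain, field-standard procedure; the package's
value is having all of them under one roof, testable end to end against a
generator with known ground truth.

## Differential expression and DEG selection

For gene $g$ with group means $\bar x_A, \bar x_B$ on the log2 scale,

$$t_g = \frac{\bar x_B - \bar x_A}{\sqrt{s_A^2/n_A + s_B^2/n_B}},$$

with Welch–Satterthwaite degrees of freedom and a two-sided p-value. No
multiple-testing correction is applied: the p-value is used only as a weak
filter (default $p < 0.05$) ahead of fold-change ranking, which is the
MAQC-style selection rule. The log2 fold change is the difference of log2
means, not the log of a ratio of linear means — consistent with RMA's
log-scale output.

Within each regulation direction, surviving genes are ranked by fold-change
magnitude; the top $L$ per direction form the DEG list (2$L$ genes). Two
conventions are fixed for determinism, because POG comparisons must be
reproducible bit for bit: ties in fold change are broken by smaller p-value,
then lexicographic gene id; genes with a fold change of exactly zero belong
to neither direction (they occur with probability zero on real data but can
arise in synthetic edge cases).

Degenerate genes where both groups have zero variance get $t=0, p=1$ when the
means agree; when the means differ the p-value is reported as its limit 0 and
the gene is listed in the result's `flagged` slot, so the caller can decide
whether to trust it.

A note on calibration: with $n=3$ arrays per group, Welch's test is known to
be conservative — its true type-I level under normal equal-variance noise is
about 0.035 at nominal 0.05 (a property of the Satterthwaite approximation at
tiny sample sizes, reproducible directly with `stats::t.test`). The test
suite checks that our vectorized implementation agrees with `stats::t.test`
decision-for-decision; users should not expect the *nominal* 5% false-positive
rate at triplicate sample sizes.

## POG

For two equal-size, direction-split lists, with $DD$ and $UU$ the numbers of
commonly down- and up-regulated genes,

$$\mathrm{POG} = 100 \cdot \frac{DD + UU}{2L}.$$

The POG curve sweeps $L$ from 1 to the largest value supportable by both
experiments (the smaller direction count after filtering, minimized over
experiments), with the x-axis conventionally 2$L$. The sweep is computed
incrementally — a shared gene enters the overlap at
$L = \max(\text{rank}_a, \text{rank}_b)$ — so the full curve costs $O(n)$
set operations rather than $O(n^2)$.

The reference band summarizes several comparison curves (e.g. each of several
platforms against a common anchor) by their pointwise mean with a pointwise
t-interval, $\bar p \pm t_{(1+\gamma)/2,\,n-1}\, s/\sqrt n$ on the shared 2$L$
support. The band construction is not uniquely determined by convention; a
pointwise t-interval over the comparison curves is the simplest defensible
choice and is recorded in the object (`nComparisons`, `level`). With the
typical $n = 4$ comparisons the band is wide; it is a visual guide, not a
formal simultaneous test.

Directional agreement is reported on three nested gene universes: *all*
common genes; genes with $p <$ cutoff in *either* experiment; and in *both*.
Stringency prunes genes whose direction estimate is noise, so agreement
should rise from *all* through *either* to *both*; the acceptance suite
verifies that ordering across seeds.

## RMA-style summarization

*Background correction* fits, per array, the convolution of an exponential
signal with normal background using the published mode-based ad hoc
estimators (background mean = refined density mode; background SD from the
spread below the mode; signal rate from the mode of the exceedances) and
replaces each intensity by $E[\text{signal} \mid \text{observed}]$. Two
numerical choices matter on heavy-tailed data: the density grid for mode
location is capped at the 99.5th percentile (a stray maximum otherwise
stretches the grid and bandwidth until the mode estimate destabilizes), and
the output is floored at $2^{-20}$ because the Mills-ratio expression cancels
to machine zero far in the left tail. The transformation is increasing in
the input, so within-array ranks are preserved.

*Quantile normalization* forces every array's sorted values onto the
across-array mean of sorted values; ties get the average of the tied ranks'
reference values. This matches `limma::normalizeQuantiles`, which the test
suite uses as an independent oracle.

*Median polish* fits log2 PM ≈ probe effect + array effect per probeset by
alternating row/column sweeps (Tukey), reporting overall + array effects as
the probeset's log2 expression. Even-count medians take the *lower* middle
value so results are bit-identical across platforms and BLAS builds;
convergence is declared when the total absolute residual changes by less than
1% (relative), capped at 10 iterations. Single-probe probesets pass through.
The sweep loop is in C++ (the one hot spot of the pipeline); an odd×odd
instance — where the lower-median convention coincides with the ordinary
median — is checked cell-for-cell against `stats::medpolish`.

Summarization is applied to one experiment (one platform's arrays) at a
time, matching standard practice of normalizing comparable arrays together.

### Quantile normalization distorts fold changes — by design of the test suite, not hidden

Because the A and B arrays are normalized *jointly*, any true difference
between the two samples' intensity *distributions* is partially absorbed by
the common reference distribution. With a noise-free generator one can
measure this in isolation: median-polish summarization alone recovers every
true fold change exactly (error < 1e-8), while inserting quantile
normalization compresses the net fold-change slope below 1 and can even flip
the apparent direction of genes sitting in the far tails of the intensity
distribution. The effect grows with the DE fraction and effect size; at the
package's default regime (70% DE genes, mean |log2 FC| 1.5) the median
per-gene distortion is ≈ 0.2 log2 units. This is a real property of RMA-style
pipelines, not an implementation artifact, and it is one reason measured
fold-change slopes come out well below the generator's compression parameter
when the full pipeline (including background correction, which additionally
shrinks low-intensity fold changes) is applied. Tests therefore assert exact
recovery for the polish step, and net-compression/rank-preservation — not
per-gene identity — for the full pipeline.

## MAS5-style QC

The *scaling factor* is target / trimmed mean of an array's linear-scale
signal, with the vendor-conventional target 500 and 2% two-sided trim (both
overridable). Values far above 1 indicate weak hybridization signal; the
package reports, never enforces.

*Detection calls* compute per-probe discrimination scores
$R_i = (PM_i - MM_i)/(PM_i + MM_i)$ and test $\mathrm{median}(R) > \tau$ with
a one-sided Wilcoxon signed rank: $p < \alpha_1$ → Present,
$p < \alpha_2$ → Marginal, else Absent. The constants $\tau = 0.015$,
$\alpha_1 = 0.04$, $\alpha_2 = 0.06$ are the vendor's published defaults and
are exposed as arguments. The exact signed-rank null distribution is used
when scores are untied and nonzero; otherwise the normal approximation with
tie correction and continuity correction (matching `stats::wilcox.test`,
the test oracle). Probesets with fewer than 3 probes are called but flagged
low-confidence.

# The synthetic generator

`simulateExperimentPair()` emulates a paired comparison of a healthy
("reference") and a degraded ("expired") platform profiling the same A/B
sample pair in triplicate. Per gene $g$:

* sample-A log2 mean $a_g \sim N(\mu_0, \sigma_0)$, default
  $N(7.8,\ 2.3)$ — the scale and spread typical of RMA log2 intensities on
  a ~8.5k-gene common-gene universe;
* true log2 fold change: zero with probability $1-\pi_{DE}$; otherwise a
  fair-coin sign and Exponential(mean = `effectSizeLog2`) magnitude. The
  config field is defined as the *mean* absolute fold change, and a
  continuous, heavy-tailed magnitude spectrum is what makes fold-change
  *ranking* meaningful — if all DE genes shared one magnitude the top-$L$
  ordering would be decided by noise and any POG curve would collapse;
* probe-level PM intensity $= 2^{a_g (+fc) + \phi_p + \varepsilon} + B$,
  with probe affinities $\phi_p \sim N(0, 0.5)$ drawn once and shared
  between platforms (the platforms' probe designs are identical), replicate
  noise $\varepsilon \sim N(0, \sigma_{rep})$ per probe and array, and
  exponential additive background $B$ (MM probes carry background only) —
  the additive-background convolution that RMA's correction step assumes,
  so the summarization tests are self-consistent.

The degraded platform differs in four ways, each a single config knob:
fold changes multiplied by `compression` (default 0.8), gene means shifted
by `intensityShiftLog2` (default −1.5) with between-gene SD multiplied by
`spreadShrink` (default 0.84), and background inflated ×4. Defaults put the
two platforms at mean log2 intensities ≈ 7.8 vs 6.3 and SDs ≈ 2.3 vs 1.93,
the regime of a healthy-vs-expired contrast; $\pi_{DE} = 0.7$ and mean
|log2 FC| = 1.5 reflect how strongly the two reference RNA samples actually
differ (a majority of genes detectably DE); $\sigma_{rep} = 0.15$ puts
between-replicate correlations above 0.99, matching the repeatability level
of technical replicates on such arrays. The background mean (30 on the
linear scale) was set so that the reference platform's Present-call rate is
high; with the ×4 inflation the degraded platform's detection loss is more
pronounced than on real expired arrays — the generator exaggerates the
qualitative signature rather than calibrating to any particular chip lot.

`expectedDegradationReport()` returns the closed-form expectations implied by
a config (per-platform mean and SD of log2 signal, the fold-change ratio =
compression, and the single-probe replicate correlation
$1/(1+(\sigma_{rep}/\sigma_0)^2)$), which the test suite compares against
empirical values at $n = 5000$ genes within 3 standard errors.

Determinism: one seeded RNG stream, consumed in a fixed order (gene-level
draws, affinities, then per-platform noise and background), so the same
config and seed give bit-identical output regardless of platform.

What the generator does *not* model: scanner spatial artifacts, batch or lab
effects, probe-sequence (GC) effects, and any mechanistic account of *why*
degraded arrays compress fold changes — compression is a free multiplicative
parameter, not a chemistry claim. Passing tests on synthetic data therefore
demonstrate correctness of the statistics and the direction of degradation
effects, not quantitative agreement with any particular real array lot.

# Numerical and design choices

* **Gene alignment** (`intersectCommonGenes`): experiments are reduced to
  genes mapped on every input platform *and* present in every matrix, in
  mapping-table row order, so all downstream paired-vector operations are
  positionally aligned. Missing values are a hard error — expression
  matrices in this workflow never legitimately contain them.
* **Problem sizes in tests**: unit tests run at 40–1500 genes; convergence
  checks at 5000; acceptance-style sweeps use the full default 8550-gene
  configuration over 20 seeds, which keeps the whole suite around a minute
  on one core.
* **Scaling-factor trim**: `floor(n * trim)` values per tail, with an error
  if the trim removes nothing — a trimmed mean that trims nothing silently
  would defeat its outlier resistance.
* **Provenance**: pipeline outputs carry a config hash (FNV-1a over the
  deparsed config, excluding the output directory) and the seed, never
  timestamps, so identical runs are byte-identical and diffable.
* **Open choice, recorded**: whether Welch tests should run on log2 or
  linear intensities is not dictated by the selection rule; log2 is used
  throughout, matching RMA output and making the fold change a difference
  of means.

# Known limitations

* POG concordance is a *surrogate* for agreement about biology: it measures
  list overlap under one selection rule, and is sensitive to the fold-change
  distribution near the selection boundary.
* The reference band assumes the comparison curves are exchangeable and
  roughly normal pointwise; with 4 curves the t-interval is wide and its
  coverage nominal at best.
* Quantile normalization's fold-change distortion (above) means per-gene
  fold-change estimates from the full pipeline are biased toward zero at
  high DE fractions; rankings, signs of well-expressed genes and list
  overlaps are far more stable than magnitudes.
* Welch p-values at triplicate sample sizes are conservative (true level
  ≈ 0.035 at nominal 0.05); the p filter is a gate, not an error-rate
  guarantee.
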