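---
title: "Ratio-based reproducibility assays for expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-based reproducibility assays for expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprepro)
```

# Why the correlation coefficient is not enough

The Pearson correlation between two replicates of an expression assay is
routinely reported as evidence of reproducibility. But Pearson r is
invariant to multiplying one replicate by any positive constant: a dataset
in which every gene disagrees by 60% between replicates can still show
r > 0.98. Three complementary diagnostics expose what the correlation
hides, and this package implements all of them plus a ratio-based
coefficient designed to replace the correlation as the primary
reproducibility measure.

1. **Inter-replicate variation fraction.** For gene $i$ with replicate
   values $x_i$ and $y_i$, the variation is the fold ratio minus one,
   $\max(x_i, y_i)/\min(x_i, y_i) - 1$. The fraction of genes with
   variation above a cutoff (0.5, i.e. "more than 50%", by convention) is
   a direct, scale-free noise summary (`interReplicateVariation()`,
   `fractionExceeding()`). The boundary is strict (`>`) by default with an
   `inclusive` flag, because both conventions appear in practice.
2. **Regression slope.** The OLS slope of one replicate on the other
   deviates from 1 under systematic bias even when r is perfect
   (`replicateRegression()`). We fit with an intercept by default —
   the convention of the plotting tools this diagnostic descends from —
   and offer `throughOrigin = TRUE` since the choice is not canonical.
   Log-scale slopes are reported when asked for, but note they understate
   multiplicative bias: $y = cx$ has log-slope 1 with the bias hidden in
   the intercept, so a log-scale slope near 1 is *not* evidence of
   equality. Genes with zeros are excluded from log-scale fits and
   counted; no pseudocount is added unless requested explicitly.
3. **Narrow-interval inspection.** Over a full dynamic range of four or
   five decades, a scatter plot visually compresses large fold errors.
   Restricting to a narrow window of the expression axis (membership by
   the per-gene replicate mean) and summarizing max/min fold deviations
   (`narrowIntervalSummary()`) shows the real per-gene noise level.

# The ratio-statistics reproducibility coefficients

The core method replaces the correlation by a replicate-substitution
analysis of inter-treatment expression ratios. For treatments $a \ne b$
and replicates $r$ of $a$, $s$ of $b$, the population
$P_{a r, b s} = \{ x_{i a r} / x_{i b s} \}_i$ has mean $M$ and standard
deviation $S$. Both orders $(a,b)$ and $(b,a)$ are kept as separate
measurements: ratios are asymmetric around 1, and the usual fix — taking
logs — is rejected deliberately because the log transform shrinks exactly
the differences the assay must expose.

Reproducibility is then probed by substituting replicates: for a fixed
source replicate $r$, the populations $P_{ar,bs}$ and $P_{ar,bs'}$ differ
only in which replicate of $b$ was used, so under perfect reproducibility

$$\frac{M(r,s)}{M(r,s')} = \frac{S(r,s)}{S(r,s')} = 1 .$$

Each statistic ratio $v$ is folded into a deviation
$d = v - 1$ if $v \ge 1$, else $1/v - 1$, which treats $v$ and $1/v$
symmetrically. The **average of all deviations** and the **standard
deviation of the deviations** are the two reproducibility coefficients:
0 under perfect reproducibility, increasing with inter-replicate noise
(the second measures how *constant* the reproducibility is across
treatments). For $n$ treatments with $r$ replicates each there are
$n(n-1)\,r^2$ populations and $n(n-1)\,r\binom{r}{2}$ comparisons per
statistic — 48 populations and 24 + 24 comparisons for a 4-treatment,
2-replicate design.

Design choices that were genuinely open, and how we resolved them:

* **Comparison pattern.** Statistic ratios are formed only between
  populations sharing the same source replicate and differing in the
  target replicate; cross-source comparisons are not formed. This is the
  replicate-substitution pattern the procedure defines, and it is what
  makes the swap-symmetry property hold (relabeling the replicates of any
  treatment leaves the coefficients unchanged).
* **Pooling.** Mean- and SD-statistic deviations are pooled into a single
  coefficient pair by default, since a single "average of deviations" is
  the headline number; a per-statistic breakdown is always carried in the
  result (`perStatistic`) because the pooled and mean-only readings are
  both defensible.
* **SD convention.** Sample (n−1) standard deviation is the default both
  for $S$ within populations and for the coefficient itself, with a
  `population` option for parity with spreadsheet workflows whose
  convention is ambiguous.
* **Degenerate SD ratios.** A comparison where either $S$ is zero (or
  undefined, for a single-gene population) is *skipped and counted*,
  never treated as 0 or infinity; a skip with exactly one zero also
  warns. Silently dropping them would hide degenerate data.
* **Gene exclusion.** Genes with zero or missing values are excluded per
  population (pairwise) by default; a `listwise` option restricts every
  population to genes positive in all samples, the convention used when a
  fixed gene universe across technical replicates is wanted.

The same idea applies within a treatment
(`withinTreatmentDeviation()`): for ordered replicate pairs $(k,l)$ the
ratio population $x_{ik}/x_{il}$ has expected mean 1 and SD 0 under
perfect reproducibility; the folded deviation of the mean, averaged over
pairs, is the within-treatment coefficient, with each population's SD
reported alongside. Two replicates give two ordered pairs with equal
deviations by symmetry; more replicates give more informative averages.

Because the coefficients are descriptive, data-dependent statistics,
they support comparisons *between pipelines on the same data* (raw versus
RPKM-corrected, say), not between experiments.

# Fold-change thresholds from the inter-replicate distribution

When reproducibility is poor, the data can still be used by filtering
significant inter-treatment changes against the empirical inter-replicate
fold-change distribution. Under the assumption that extreme
inter-replicate variation is random rather than gene-specific, the
within-treatment replicate pairs provide a null: the threshold is the
smallest *observed* fold change $t$ with empirical frequency
$P(FC \ge t) < \alpha$ for an acceptable false-positive likelihood
$\alpha$ (0.05 or 0.01). Candidates are restricted to observed values
because the empirical frequency is flat between them; when even the
maximum observed value is too frequent, the threshold is placed just
above the maximum and flagged. At application time
(`applyThreshold()`), significant genes with fold change *at or below*
the threshold are reported as sub-threshold — "the same or lower change
than replicates show" — and only strictly larger changes pass.

Fold-change distributions from several replicate pairs are pooled by
default (per-pair thresholds are available through the `pairs` argument),
and `groupedThresholds()` computes bin-wise thresholds by gene length or
mean abundance for data where short or low-abundance genes are
systematically noisier; bins with fewer than 20 genes are computed but
flagged.

# Normalization steps

Four corrections are provided to re-assess reproducibility after
adjustment: `rpkm()` ($c \cdot 10^9 / (N \cdot L)$), `totalCountScaling()`
(library-size equalization), `referenceGeneScaling()` and
`quantileNormalize()` (delegated to the standard mean-of-order-statistics
algorithm with rank-average ties). Reference-gene scaling anchors each
treatment on its first replicate and multiplies every other replicate by
the mean over reference genes of (anchor value / replicate value); the
anchor choice is arbitrary, so it is recorded in the output metadata.
A useful invariant ties this module to the QC module: any correction that
is a pure per-sample scale factor repairs the slope and the variation
fraction while leaving Pearson r exactly unchanged — the dissociation
that motivates the whole package.

# ORF-length correction of protein quantities

Even with no post-transcriptional regulation at all, equal transcript
induction does not produce equal protein induction when coding-sequence
lengths differ: translating a transcript twice as long takes roughly
twice as long, so the shorter gene's protein accumulates twice as fast.
Correlating transcript with raw protein quantities therefore understates
the transcript–protein agreement. The correction factor
$CF_i = L_i / \min_j L_j \ge 1$ multiplies the protein value:
$CPF_i = PF_i \cdot CF_i$ (`correctionFactors()`, `correctProtein()`).
The correction always multiplies protein values — never divides
transcript values — to keep its direction unambiguous, and applies
identically to fold changes and raw quantities.
`correlationShift()` reports Pearson and Spearman coefficients before and
after correction; coefficients on constant vectors are reported as
undefined (`NA`), never 0. The correction is deliberately simple: no
elongation-rate, ribosome-density-ramp or half-life modeling is
attempted, and results should be read as removing one identified
technical bias, not as isolating pure post-transcriptional regulation.

# The synthetic-data generator

`simulateExpression()` draws gene baselines log-normal
(log-mean $\ln 100$, log-sd 1 by default — a realistic four-decade
dynamic range for bulk expression data), applies per-treatment
multiplicative effects, and multiplies log-normal replicate noise with
log-sd $\sigma_{rep}$. Multiplicative noise is the right shape here
because every statistic in the package is ratio-based, and it makes noise
levels directly interpretable: the probability that a replicate pair
disagrees by at least $f$-fold is $2\Phi(-\ln f/(\sigma_{rep}\sqrt 2))$,
inverted by `noiseSdForExceedance()` (e.g. $\sigma_{rep} \approx 0.632$
puts 65% of genes beyond 1.5-fold disagreement). With
$\sigma_{rep} = 0$ replicates are bit-identical and every reproducibility
deviation is exactly 0 — the anchor for parameter-recovery tests. All
randomness flows through an explicit seed and the caller's RNG state is
restored afterwards.

`simulateProteinTranscript()` implements the length-coupled translation
mechanism ($PF = p/CF \times$ noise, with intrinsic response $p$
defaulting to the transcript fold), so that zero-noise generation is
inverted *exactly* by `correctProtein()` — a closed loop between
generator and estimator.

What the generator does **not** emulate: count discreteness and
sequencing-depth effects (no negative-binomial dispersion, no read-level
error model), gene–gene correlation, length- or abundance-dependent noise
(except when constructed explicitly, as the grouped-threshold tests do),
and batch structure. Passing tests on synthetic data therefore validate
the algebra and the statistical behavior of the estimators under the
stated noise model, not their performance on any particular sequencing
protocol.

# Numerical conventions and problem sizes

Ratios are computed in double precision with no pseudocounts; genes with
zeros are excluded per operation and counted rather than patched.
Reports are written with 15 significant digits so read→write→read round
trips are exact to at least 12 digits. The test suite runs entirely on
in-code synthetic fixtures: property tests use 200+ random designs of up
to 3 treatments × 3 replicates × 5 genes checked against a brute-force
enumeration oracle, calibration checks use 10,000 genes, and workflow
checks use 500–2,000 genes — sizes chosen so the full suite completes in
a few minutes on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances.

# Limitations

* The coefficients are descriptive; no sampling distribution or test is
  attached to them, and they must not be compared across experiments.
* The fold-change threshold assumes exchangeable inter-replicate noise
  across genes; the grouped variant relaxes this only bin-wise.
* The ORF-length correction ignores ribosome occupancy/density,
  initiation/elongation efficiency and protein half-life, all of which
  also shape the transcript–protein relationship.
* Differential-expression calling is out of scope: `applyThreshold()`
  consumes a significance flag produced by an external DE tool.
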