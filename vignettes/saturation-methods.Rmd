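---
title: "How deep is deep enough? Saturation analysis for 3' mRNA-Seq phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How deep is deep enough? Saturation analysis for 3' mRNA-Seq phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satseq)
```

## The problem

3' mRNA-Seq sequences one poly-A-proximal fragment per transcript, which
removes gene-length bias and makes per-gene read counts directly
comparable without length normalization. Because each molecule
contributes a single read, useful expression phenotypes can be obtained
at a fraction of the depth a whole-transcriptome library needs — but
how small a fraction? Sequencing too deep wastes money on every sample
of a population-scale phenotyping effort; too shallow, and genes and
differential-expression signal are missed. `satseq` answers the
question empirically for a given dataset: thin the full-depth libraries
to a ladder of depths, recompute every detection metric at each depth,
benchmark against the full-depth result, and fit a saturation curve
whose analytic flattening point is the recommended depth.

## Downsampling as hypergeometric thinning

Read-level subsampling tools draw reads without replacement. For a
sample whose reads have already been assigned to genes, drawing `d` of
its `D` reads without replacement induces a multivariate hypergeometric
distribution on the per-gene counts. `downsample_sample()` and
`downsample_matrix()` therefore draw multivariate hypergeometric
vectors directly (sequential conditional `rhyper()` draws), which is
the exact count-level equivalent of read subsampling: column totals hit
the target depth exactly, and `E[thinned count] = count * d / D`. A
`with_replacement` (multinomial) mode is available for comparison.

Reproducibility is handled with deterministic substreams: the random
stream for a grid cell is derived by hashing `(replicate seed, depth)`,
so the same call always yields the same matrices regardless of
evaluation order. `downsample_coupled()` additionally offers *nested*
draws (one permutation of read slots per sample, truncated at each
depth) so that monotonicity properties — a gene detected at 0.5M reads
stays detected at 12M — hold exactly, which the test-suite exploits;
marginally each coupled depth is still an exact hypergeometric draw.

Depths that exceed a sample's total are an error by default; an
opt-in `infeasible = "cap"` policy thins such samples to their own
total instead, which mirrors how real experiments handle libraries
that cannot reach the deepest rung of the ladder.

## Detection metrics

Three nested gene sets are tracked, all tunable via arguments:

* **Expressed** (`expressed_genes_*`): count ≥ 1 in a sample
  (per-sample) or in ≥ 1 sample (dataset union). Deliberately liberal.
* **Informative** (`informative_genes()`): count ≥ 10 in at least 50%
  of samples (ceiling for odd n). This is the core set stable enough to
  serve as population-level molecular phenotypes.
* **DEGs**: genes called at BH-adjusted p < 0.05 by the NB stage below,
  with no fold-change cutoff.

`prevalence_distribution()` reports how many genes are detected in
exactly k individuals — the long tail of privately detected genes is
what separates the expressed from the informative set.

## The negative-binomial DE stage

The DE stage is a deliberately transparent stand-in for heavyweight DE
frameworks: median-of-ratios size factors (with a positive-counts
fallback for sparse, heavily thinned matrices), method-of-moments
dispersion estimation shrunk toward a fitted `a0 + a1/mu` trend, and a
per-gene NB GLM with log link. It has no Cook's-distance filtering, no
independent filtering and no LFC shrinkage, so DEG counts are not
claimed to be interchangeable with any specific framework's — what
matters for the saturation analysis is that the same, well-calibrated
test is applied at every depth.

Two design choices deserve explanation:

* **Cell-means parameterization.** The two group means are fitted as
  separate intercept-only GLMs, which makes the group contrast exactly
  antisymmetric under label swaps (bit-identical p-values, negated
  LFCs) — a property a shared-intercept IRLS only achieves up to
  floating-point noise.
* **t reference for the Wald statistic.** With the dispersion plugged
  in, the Wald statistic at realistic sample sizes is t-like, not
  normal: with n = 29 samples the normal reference rejects a true null
  at rate `2 * P(T_27 > 1.96) ≈ 0.060` rather than 0.050. The p-value
  therefore uses a t distribution with `n - 2` degrees of freedom. A
  calibration study at the design size used throughout this package
  (14 vs 15 samples, dispersion 0.1, 2,000 null genes) measured
  empirical type-I error of 0.043–0.051 at nominal 0.05 across seeds.
  The dispersion shrinkage weight (default 0.5) was chosen in the same
  study; measured calibration was flat in the weight, so it is not
  doing the calibrating — the t reference is.

## Benchmarking against full depth

The full-depth result is taken as the truth set. For each depth and
replicate seed, `confusion()` counts TP (in both), FP (subsample only)
and FN (full data only), and `precision_recall_f()` computes

\[
P = \frac{TP}{TP+FP},\qquad R = \frac{TP}{TP+FN},\qquad
F = \frac{TP}{TP+\tfrac12(FP+FN)},
\]

with `NA` (not 0) for degenerate denominators so that "nothing called"
is distinguishable from "everything wrong". Group comparisons (e.g.
two library-preparation kits) use Welch's unequal-variance t-test.

## The saturation curve and its plateau

Set sizes as a function of depth are fitted with the classical
asymptotic regression model

\[ y = y_{max} + (y_0 - y_{max})\, e^{-e^{lrc} x}, \]

where `ymax` is the asymptote, `y0` the response at zero depth and
`lrc` the natural log of the rate constant. All replicate points are
pooled into one fit (not averaged first). Fitting is
Levenberg–Marquardt nonlinear least squares started from a self-start
heuristic (`ymax0 = 1.05 max(y)`, `y00 = min(y)`, `lrc0` from OLS of
`log(ymax0 - y)` on `x`), with the classical self-starting initializer
as a fallback. Convergence failures carry the start values in the
error; decreasing data yield a flagged non-saturating fit rather than
a silent plateau.

The saturation depth is where the fitted slope drops to a marginal-gain
threshold, by default `1e-4` genes per read — one additional gene per
10,000 extra reads per sample:

\[ x_{plateau} = -\frac{\ln\left(\frac{-t}{y_0-y_{max}}\right) - lrc}{e^{lrc}}. \]

This closed form is exact; the test-suite verifies that the model
derivative evaluated at `x_plateau` returns the threshold to a relative
1e-9 over a thousand random parameter draws. When `x_plateau` exceeds
the largest observed depth the result carries an `extrapolated` flag —
a plateau extrapolated beyond the data should be read as a lower bound
on the required depth, not a measurement.

`marginal_gain()` converts any two depths into the predicted gain in
the response, which is how "sequencing to full depth would only add N
genes" statements are produced.

## Variant filtering and 3' positional bias

3' mRNA-Seq reads can also be used to call genomic variants, albeit
only near 3' gene ends. `satseq` consumes an already-called VCF
(per-sample `AD`/`DP` required) and applies three tiers:

1. **Site hard filter** (`site_hard_filter()`): fail when any present
   annotation violates `QD < 20`, `FS > 20`, `MQRankSum < -12.5`,
   `ReadPosRankSum < -8`, `SOR > 5`. Missing annotations never fail a
   record — the convention of the calling toolchain — and fully
   unannotated records are flagged.
2. **Lenient** (`filter_lenient()`): keep records with
   `DP_total >= 10` summed across samples and any alternate-allele
   support.
3. **Stringent** (`filter_stringent()`): per alternate allele, require
   support in at least one sample (`AD >= 2`, or allele ratio `>= 0.1`
   with `DP > 10`), plus a recalculated total depth `>= 5`. The
   recalculated depth defaults to the sum of AD entries (depth
   recomputed from allele depths); a `dp_sum` strategy switch uses the
   DP field instead. Multiallelic records are filtered per allele and
   never split.

The stringent survivors are in practice a subset of the lenient ones
at these defaults, but this is not a theorem: a site supported by two
alternate reads at recalculated depth 5–9 passes the stringent tier
while failing the lenient total-depth floor. At realistic total depths
(tens of reads across samples) such sites essentially never occur,
which is how the nesting is tested.

Positional analyses are strand-aware: `relative_position()` maps a
variant to `r in [0, 1]` with 0 at the 5' end and 1 at the 3' end
(reflected for minus-strand genes; single-base genes map to 0 by
convention), and `position_histogram()` bins `r` with a right-closed
final bin. Known-site overlap is allele-aware
(`chrom:pos:ref:alt` exact match) with an opt-in position-only mode.

In the saturation pipeline, lower depths are emulated by binomial
thinning of every AD entry (and the non-allelic remainder of DP) at
`d / D` before re-applying the stringent filter. This is an explicit
approximation of re-calling at lower depth: it cannot move, gain or
re-genotype sites, only remove support. Its fidelity to a true
re-call is not claimed, and the variant metrics it produces should be
read accordingly.

## The synthetic-data generators

Every stage can be exercised without external data:

* `simulate_counts()` draws NB counts (`variance = mu + alpha mu^2`,
  single `alpha`, default 0.1 — the standard RNA-seq overdispersion
  form, recoverable by the DE stage) for 15,000 genes over 27 samples
  in two conditions (14 + 13), with log-uniform baseline abundances
  spanning `log(0.01)` to `log(1000)` relative units. The wide
  log-uniform range creates the long prevalence tail that makes the
  informative-gene threshold meaningful. 10% of genes carry a true
  log2 fold change of 1, split evenly up/down, and expected library
  size is 12.5M reads — the scale of a full-depth 3' library. These
  defaults describe a realistic whole-blood-style design; real blood
  count distributions are not published for this exact setting, so
  the defaults are stated choices, not calibrated fits.
* `simulate_saturation_observations()` draws replicate observations
  exactly from the asymptotic model plus Gaussian noise — the
  round-trip oracle for the fitter.
* `simulate_gene_models()` and `simulate_variant_records()` build a
  stranded annotation and called-variant records whose intragenic
  positions follow density `(b+1) r^b` toward the 3' end (`b = 2` by
  default; `b = 0` is uniform), with Poisson per-sample depths (mean
  20), Beta-distributed site allele fractions, and configurable
  fractions of records constructed to fail the site filter or carry
  zero alternate support.

What the generators deliberately do **not** emulate: mapping artefacts,
sample quality variation, correlated (paired animal) designs,
gene-length effects, linkage between variants, or any read-level
process. Passing tests on synthetic data therefore validate the
*machinery* — thinning, metrics, fitting, filtering — not the
biological claims one would make about a particular real dataset.

## Problem sizes and numerics

The test-suite and the acceptance script run at deliberate scales:
study-scale simulation (15,000 genes x 27 samples at 12.5M reads, the
full 7-depth x 10-seed grid) for the headline quantities, and smaller
designs (a few thousand genes, 5-10 samples, proportionally scaled-down
depth ladders) for properties that do not depend on scale. The
end-to-end plateau check compares the pipeline against an exact
analytic oracle: the expected union-expressed count under
hypergeometric thinning evaluated on a dense depth grid, fitted with
the same model. Numerical details worth knowing:

* NLS convergence tolerance is 1e-12 on the relative SSE change
  (500 iterations max); IRLS in the DE stage stops at 1e-10 relative
  change in coefficients, with means clamped to `[1e-10, 1e12]` and
  log-means to `[-30, 30]` to keep one-group-zero genes finite.
* Dispersions are floored at 1e-8; a constant gene floors rather than
  errors.
* BH adjustment excludes untested genes from the denominator; the
  count of untested genes is reported in `glance()`.
* Seeds: every stochastic function takes an explicit seed and is a
  pure function of it; grid substreams are derived by integer hashing
  so results are order-independent.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_counts(seed = 1)
report <- run_saturation(sim$counts, condition = sim$condition, master_seed = 1)
glance(report) # per-metric fit + plateau
autoplot(report) # points, fitted curves, plateau dots
```

## Known limitations

* The DE stand-in will not reproduce DESeq2/edgeR DEG counts exactly;
  only its calibration and its internal consistency across depths are
  validated.
* Variant-depth thinning approximates re-calling; true re-calls can
  both gain and lose sites in ways thinning cannot.
* Plateaus beyond the observed depth range are extrapolations and are
  flagged as such.
* The asymptotic model is a single exponential; detection curves with
  two well-separated time scales (e.g. a large near-silent gene
  cohort) will fit it imperfectly, which shows up as a
  depth-grid-dependent plateau.
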