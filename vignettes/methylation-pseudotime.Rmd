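---
title: "Methylation pseudotime and the Epigenetic Pacemaker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation pseudotime and the Epigenetic Pacemaker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudopace)
```

# Overview

`pseudopace` orders DNA-methylation profiles along the human aging process in
two independent, form-free ways — arc-length pseudotime along an inferred
trajectory, and the latent epigenetic state of the Epigenetic Pacemaker —
and then asks which analytic function of chronological age best describes
the ordering.  This vignette is the package's own account of the models, the
synthetic world used to test them, and the numerical decisions taken where a
design was genuinely open.  It states no empirical result that the test
suite or the acceptance script does not itself compute.

# The pipeline stage by stage

## Preprocessing

**Site selection.**  Training-split Pearson correlation between each site's
beta values and age; sites with `|PCC|` *strictly* greater than a threshold
are retained (0.4 by default, blood-like; 0.7 brain-like).  Zero-variance
sites get an undefined (`NA`) correlation and are excluded, never coerced to
a number.

**Probe-type quantile normalization.**  Illumina 450k type-I and type-II
probes have different measurement distributions, so normalization is done
within design type.  The reference is built from training samples only: each
training column is sorted within type and the per-rank median taken.  Every
split — train, validation, test — is then mapped onto that reference, which
both removes batch shifts and prevents test-set leakage into the reference.
Open choices we fixed: tied input values receive the mean of the reference
values at their tied ranks (the map is deterministic and ties stay tied);
when a sample has fewer probes than the reference (after subsetting),
reference quantiles are linearly interpolated.

## Embedding and clustering

PCA with centering only (no variance scaling — beta values share a scale and
the dominant age signal would be diluted by scaling near-constant sites).
Two components by default.  PCA signs are arbitrary, so each component is
oriented to correlate non-negatively with training age; this affects nothing
downstream except reproducibility of plots and serialized models.

Clustering uses a Gaussian mixture fitted by EM from a seeded k-means
partition.  Six covariance families (spherical/diagonal/full, each shared or
free across clusters) approximate the larger zoo of the usual GMM packages;
cluster count and family are chosen by BIC
(`n_params * ln(n) - 2 * loglik`, minimized; selection is invariant to the
sign convention).  Ties break toward smaller `k`, then family order.
Degenerate covariances are floored at 1e-6 on the eigenvalues and flagged on
the model rather than failing the fit.

## Trajectory and pseudotime

A minimum spanning tree over the mixture means (Prim's algorithm,
lexicographic tie-breaks) gives the cluster-level skeleton.  The start
cluster is the one with minimum mean training age — pseudotime should grow
with biological progression and no other anchor is available.  Only
single-lineage topologies are modelled: a tree with a branch (any vertex of
degree ≥ 3, or a start cluster in the middle of the path) raises an explicit
unsupported-topology error instead of silently choosing a lineage.

The path of cluster centers seeds a principal curve: project all samples
onto the current polyline, order them by arc position, smooth each
coordinate against arc position, re-discretize to 100 control points, and
repeat until the mean squared projection distance stabilizes (relative
tolerance 1e-6, at most 50 rounds).  The smoother is local-linear
(`lowess`, span 0.3, no robustness iterations) rather than a plain running
mean: a running mean shrinks curve endpoints inward even for exactly
collinear data, whereas the local-linear fit reproduces a line exactly.
With a single cluster the curve is seeded with the principal axis of the
point cloud.

Pseudotime is the arc length from the curve start to the sample's orthogonal
projection; points projecting beyond the endpoints are clamped to
`[0, total_length]`.  Clamping (rather than extending the curve) keeps
pseudotime bounded; the consequence is that extreme-age samples beyond the
training envelope saturate rather than extrapolate.  Held-out samples are
projected onto the frozen embedding and curve; nothing is refitted.

## The Epigenetic Pacemaker

The EPM models each value as `m_ij = m_i0 + r_i * s_j + e_ij` and minimizes
total squared error by alternating two exact conditional minimizers: per-site
OLS of methylation on states, and the per-sample closed form
`s_j = sum_i r_i (m_ij - m_i0) / sum_i r_i^2`.  Both half-steps are exact,
so the RSS is non-increasing at every half-step and the algorithm is
deterministic given the initialization — there is no stochastic E-step.
Convergence is declared on relative RSS change below 1e-6 (parameter-change
criteria behave erratically along the model's flat direction, next
paragraph).

The model has an exact affine ambiguity: `s -> alpha*s + gamma` with
compensating `(m_i0, r_i)` leaves the fit unchanged.  Initializing states at
chronological age selects a member of that family; the fitted states
therefore live on an age-like scale, *not* on the scale of any particular
latent variable that generated the data.  Correlation-based comparisons
(which is how states are used downstream) are unaffected.  The test suite
verifies the pinning directly: on data generated with states equal to the
initialization scale, the fitted states regress on truth with slope within
[0.9, 1.1].

Cross-validation uses age-stratified folds (consecutive age-ordered blocks,
fold labels permuted within block).  For test-set prediction the EPM is
refitted on the full training split; the five fold models are kept for
diagnostics only, since no principled way of merging fold-wise site
parameters is stated anywhere.

## Trend-form comparison

Five candidate forms of age: quadratic, logarithmic, square-root,
exponential `a(1 - e^{-bx})`, and the sum of two exponentials
`a(1 + c - e^{-bx} - c e^{-dx})` (plus plain linear, available but not part
of the default comparison).  Numerical decisions:

* Transformed-linear forms are solved by exact least squares (QR).
* The exponential families are fitted by **variable projection**: the
  amplitude coefficients enter linearly once the rates are fixed
  (`y = u(1 - e^{-bx}) + v(1 - e^{-dx})` with `u = a`, `v = a*c`), so the
  profiled RSS is optimized only over the rates — a grid
  `{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 2}` (pairs with `b < d` for the
  double form) followed by Nelder-Mead refinement on log-rates from the
  three best grid points.  This replaces a damped Gauss-Newton on all four
  coefficients; the profiled problem is two-dimensional, bounded, and far
  better conditioned, and the tests verify the result is the least-squares
  optimum against the generating parameters.
* The double form is invariant under swapping `(b, u)` with `(d, v)`;
  reported fits are normalized to `b <= d`.
* The logarithmic form is undefined at age 0, which the cohorts contain;
  ages are floored at 0.1 years for that form only.
* `R²` uses the mean-only null model (`1 - RSS/TSS`) for all forms, with
  `R² = 0` by convention when the response is constant.
* AIC is the Gaussian maximum-likelihood form
  `n ln(2π RSS/n) + n + 2(p + 1)`, counting the error variance as a
  parameter — the convention of R's standard `AIC()` on least-squares
  models.  `RSS = 0` yields `-Inf`, a marker rather than an error.

Exponential rates convert to doubling times `ln(2)/b` for comparison with
the Gompertz mortality coefficient.  Because it is genuinely ambiguous which
of the two rates of a double-exponential fit is "the" timescale, the report
prints doubling times for both.  A caution the worked example illustrates:
when the slow rate collapses toward zero the corresponding component is
indistinguishable from a linear term over a human lifespan, and its doubling
time is meaningless (it will print as an astronomically large number); the
other rate is then the interpretable one.

# The synthetic world

The generator emulates a blood-like 450k cohort: ages uniform on 0–99 (an
optional right-skewed mixture mimics adult-heavy cohorts; real cohort age
densities are not published, so uniform is the default), a latent epigenetic
state following the sum-of-two-exponentials trend with the whole-blood
coefficients (a = 14.487, b = 0.019, c = 0.307, d = 0.105; latent range
roughly 0–16.7 over a lifespan), and per-site linear responses
`beta = m_i0 + r_i * s + noise` clipped to `[0, 1]`.

Defaults and why:

* `n_sites = 2000`, half age-associated.  Site rates have random sign
  (methylation gains and losses both occur) and magnitude uniform in
  `[0.015, 0.04]` per state unit — at beta-noise 0.02 this puts the
  per-site |correlation| with the latent state at roughly 0.95–0.99,
  comparable to sites passing a stringent age filter.
* Intercepts for responding sites are drawn so the noiseless mean stays
  inside `[0, 1]` across the cohort's state range whenever the configured
  ranges allow it; otherwise the draw falls back to the raw intercept range
  with a warning, and clipping distorts the linear response (the truth
  object always records the pre-clipping parameters).  Non-responding sites
  get intercepts in `[0.1, 0.9]`, away from the clip boundaries.
* `noise_sd = 0.02` beta units.  The noise magnitude of real arrays at
  selected sites is not published; 0.02 is a modelling choice, exposed in
  the config and varied in tests.
* `state_noise_sd = 0` by default: inter-individual variation enters through
  beta noise, and the acceptance-scale cohort specifies none on the state.
* Splits 0.3/0.1/0.6 (train/validation/test), echoing the brain cohort's
  138/70/467 proportions, assigned by walking the age-ordered samples and
  giving each to the split with the largest proportional deficit (capped at
  largest-remainder targets) — exact split sizes and near-nominal
  proportions in every age window.

What the generator does **not** emulate: raw array intensities, batch
effects between series, cell-type composition shifts, missing values, or
spatial/sequence correlation between probes.  A green end-to-end test
therefore establishes that the pipeline recovers a latent monotone aging
signal under idealized, independent Gaussian noise — not that it is robust
to the full mess of real cohort heterogeneity.

# Determinism and serialization

Every stochastic step takes a seed, derived from one global pipeline seed,
and seeded code restores the caller's RNG state.  Identical configs produce
bit-identical cohorts, fits and serialized outputs; per-stage timings exist
only in the in-memory report so that serialized reruns compare equal
byte-for-byte.  All artifacts are plain TSV/text written with 10 significant
digits, which round-trips losslessly at that precision.

# Known limitations

* Single lineage only; branching topologies error out by design.
* Pseudotime saturates at the curve ends (clamping, no extrapolation).
* The EPM state scale is only meaningful relative to its initialization.
* The trend comparison assumes i.i.d. Gaussian residuals for its AIC; with
  heteroscedastic pseudotime residuals the ranking is a heuristic, as it is
  in the analyses it mirrors.
* The six-family GMM search is a subset of the full covariance-model zoo;
  on data whose best description lies outside it, BIC selection lands on
  the nearest available family.
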