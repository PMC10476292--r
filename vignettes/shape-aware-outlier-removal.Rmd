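---
title: "Shape-aware univariate outlier removal with Tukey g-and-h models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-aware univariate outlier removal with Tukey g-and-h models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ghoutliers)
```

## The problem

Univariate outlier screening in biomedical and epidemiological tables
usually fits a reference model to each feature and removes values beyond a
model percentile. The classical rules (IQR fences, MAD, mean ± 3 SD) all
assume the feature is a transformed normal: under normality the fence
`Q1 - 1.5 IQR` sits at about `-2.7` standard deviations and removes about
0.7% of the data, but on skewed, heavy-tailed, discrete, monotonic, or
multimodal features the same fences remove far too much or far too little.
Multivariate detectors do not solve this: a single extreme coordinate in a
20-dimensional vector barely moves any multivariate distance, so columnwise
outliers must be handled columnwise.

`ghoutliers` implements a shape-aware columnwise procedure. Each feature is
first classified by the shape of its distribution, then transformed to an
approximately modelable scale, fitted with a flexible four-parameter model,
and trimmed outside the fitted model's central 99.3% coverage region, so
that about 0.7% of clean, well-modelled data is removed regardless of the
feature's shape.

## Building blocks

### Asymmetrical outlyingness and the probit rescale

The ASO score divides each point's deviation from the median by the
half-interquartile spread of that point's own side:
`s_i = (x_i - m) / (Q3 - m)` above the median, `(x_i - m) / (m - Q1)` below.
It is location/scale free, rank preserving, and makes the two sides of a
skewed distribution comparable (`s = 1` at Q3, `s = -1` at Q1). The signed
scores are then squeezed into (0, 1) by a range-plus-margin affine map with
margin `delta = range / (2 n)` and probit transformed (`qnorm`). If the
scores were uniform the result would be exactly normal — the property holds
under any affine rescale of a uniform, which is why the rescale is a free
choice; the margin keeps the probit finite at the sample extremes. For most
real shapes the result is *not* normal but a skewed/heavy-tailed
transformation of a normal, which is exactly what the Tukey g-and-h family
models. Both steps are monotone and recorded, so model-scale cutoffs map
back to original units.

Discrete features routinely collapse one half-spread to zero; the other
half substitutes, and if both halves vanish while the feature still has
spread, half the central 10–90% spread is used. These substitutions keep
Poisson- and negative-binomial-like columns analyzable.

### The Tukey g-and-h model and percentile regression

The family transforms a standard normal `Z` as
`x = A + B ((exp(gZ) - 1) / g) exp(h Z^2 / 2)`; `g` controls skew, `h >= 0`
tail heaviness, and `g = h = 0` recovers `N(A, B^2)`. `|g| < 1e-8` switches
to the analytic `g -> 0` limit to avoid catastrophic cancellation. The
quantile function is the transform of `qnorm`; the density and CDF invert
the transform numerically (grid interpolation plus damped Newton, with a
bracketing fallback), noting that `h = 0, g != 0` bounds the support on one
side.

Estimation uses a 100-point percentile grid at `(i - 0.5)/100` rather than
two quartile-style anchor points, which keeps discrete features from
destabilizing the estimates:

* `A` is the sample median (all quantiles use linear interpolation of order
  statistics, R type 7 — one convention fixed package-wide);
* `g` is a weighted median of the per-pair estimates
  `log((x_p - A)/(A - x_{1-p})) / z_p` over symmetric pairs (invalid pairs
  with non-positive half-spreads are dropped);
* `B` and `h` come from the weighted linear regression
  `log y_p = log B + h z_p^2 / 2`, where `y_p` is the spread-based response
  with its `g -> 0` limit.

Two declared modifications, both configurable: regression/median weights
grow linearly toward the upper tail (`w_p = 1 + 2c(p - 0.5)`, `c = 1`), so
the tail — the part that decides cutoffs — fits well even when the bulk fit
is imperfect; and shrinkage `g <- 0.95 g`, `h <- max(0, 0.95 h)` biases the
shape parameters toward 0, guarding against overfitting discreteness. The
magnitudes (c and the 5% shrinkage) are package choices: only the direction
of both corrections is prescribed by the method, and both are exposed as
arguments.

### Shape classification

The dip statistic — the minimal sup-norm distance between the empirical CDF
and any unimodal CDF — is computed by the classical iterative
greatest-convex-minorant / least-concave-majorant algorithm (in C++; uniform
data attains the lower bound `1/(2n)`). Its null distribution is calibrated
by resampling 30 samples of the same size from the *closest unimodal CDF*
itself, reconstructed as a piecewise-linear CDF from the final hull touch
points with a straight bridge across the modal interval and inverse-transform
sampled. A sample is multimodal when its dip exceeds all 30 null statistics
and an absolute floor of 0.0001 (multimodality barely visible by eye).
Samples with fewer than 60 distinct values skip the test — the gate targets
discreteness, so distinctness is exact equality. Resampling from a
continuous piecewise-linear CDF slightly understates the null dip for very
discrete data, which the 60-unique gate and the absolute floor absorb.

Routing: (1) if the raw sample *or* its ASO-probit transform tests
multimodal, the sample is MULTIMODAL — the transform is tested because a
badly transformed (e.g. strongly monotonic) distribution shows up as lumpy
scores even when the raw data are unimodal; the "transformed distribution"
of the dual pre-test is read as the ASO-probit of the full sample, the only
transform defined at that point of the procedure. (2) Otherwise, if the
half-sample-mode estimate lies within 5% of the range of either boundary,
the sample is mirrored about that boundary's extremum and re-tested: a
mirrored monotone density is unimodal, so a negative test means MONOTONIC.
The 5% edge fraction only gates whether the mirror branch is tried — the
mirrored dip test is the arbiter. (3) Otherwise UNIMODAL_TWO_SIDED.

### Branch handling and cutoffs

* **MONOTONIC**: mirror about the peak edge (size 2n, exactly symmetric),
  ASO-probit, percentile fit, flag original points beyond the model's
  two-sided coverage bound. The outward tail of the mirrored set consists of
  original points only, so the expected removal is `1 - coverage` of the
  originals.
* **UNIMODAL_TWO_SIDED**: split at the half-sample mode (points equal to the
  mode belong to both sides), mirror each side about the mode, fit each side
  separately — the mirrored sets are exactly symmetric, so each side's fit is
  a pure tail model with `g = 0` — and flag each side beyond a bound whose
  tail level `t = (1 - coverage) n / (4 n_side)` calibrates each side's
  expected removal to `(1 - coverage)/2` of *all* points. A side with fewer
  than `min_side_points` (default 50, half the percentile grid) falls back to
  MONOTONIC handling of the whole sample.
* **MULTIMODAL**: ASO-probit the full sample and fit a bimodal g-and-h
  mixture by stochastic EM. The E step computes responsibilities from the
  current component densities (log-space); the M step draws hard Bernoulli
  assignments from the responsibilities, re-estimates the weights as assigned
  fractions, and refits each component by percentile regression with
  shrinkage on. With growing n the stochastic M step converges to the
  responsibility-weighted (standard EM) M step, which is also implemented
  and used as an agreement check in the tests. Initialization splits the
  scores at the midpoint of the two tallest histogram peaks (fallback:
  median) — the procedure is not described in the source method, so this is
  a declared choice; iteration stops when the relative change in mean
  log-likelihood stays below 1e-4 for 3 consecutive iterations (cap 100),
  and the highest-likelihood model seen is returned. Exactly two components
  are fitted: three or more modes are rare, and extra components tend to fit
  discreteness rather than true modes. If a component collapses below 100
  points the fit falls back to a single model. Points are flagged where the
  mixture CDF lies outside `[(1-c)/2, 1-(1-c)/2]` — only the outer tails;
  inter-mode valleys are never flagged.

Cutoffs are mapped from the model scale to original units by inverting each
monotone step (probit rescale, ASO scaling, mirror fold), and the mask is
computed by strict comparison in original units — ties at a cut are kept,
a conservative tie-break that matters for discrete data.

Before any of this, the sample is oriented so that its third central moment
is nonnegative (results are mapped back afterwards). Every later step is
exactly equivariant under affine maps and reflection, but the seeded
bootstrap and EM assignment draws are not; the canonical orientation makes
detector masks exactly invariant under `x -> a x + b` (`a > 0`) and
`x -> -x`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `coverage` | 0.993 | central model mass kept; 0.35% per tail, ~0.7% removed from clean well-modelled data |
| `min_unique_column` | 10 | distinct-value gate for analyzing a column |
| `dip_n_boot`, `dip_threshold`, `dip_min_unique` | 30, 1e-4, 60 | dip-test bootstrap size, absolute floor, discreteness gate |
| `edge_frac` | 0.05 | mode-at-edge gate for trying the monotonic branch |
| `grid_size`, `upweight` | 100, 1 | percentile grid and upper-tail weight slope |
| `shrink_g`, `shrink_h` | 0.05 | shrinkage of g and h toward 0 |
| `min_side_points`, `min_component_points` | 50, 100 | side-split and EM-component floors |
| `seed` | `NULL` | makes masks fully deterministic |

## What the simulations emulate — and what they do not

The packaged generators reproduce the benchmark's synthetic designs: ten
distribution families (lognormal, powered exponential, power, Poisson,
negative binomial, Tukey-g/-h/-gh, beta with alpha = 2, and ten declared
non-standard mixture shapes) at ten parameter values each; outlier injection
replacing 300 random points with `p99.5 + eps` (one-sided) or half each at
`p99.75 + eps` and `p0.25 - eps` (two-sided), `eps ~ U(0.5 sd, 2 sd)` — the
lower anchor is the printed 0.25th percentile; three diagnostic series
(trimodal normal mixtures with spacings 5 to 33, Tukey-g skew 0.015 to 0.75,
powered exponentials 1.03 to 2.5); and the 20-column scheme replacing 1% of
cells with values more extreme than every clean scalar. The per-family
parameter grids are declared configuration (only the diagnostic-series grids
are printed in the source); the non-standard shapes are labelled
approximations. Injected outliers are synthetic point contamination at known
positions: passing these tests shows correct calibration and tail modelling
under known ground truth, not robustness to structured artifacts (batch
effects, heaping, truncation) that real tables contain. Sample sizes in the
tests (3e4 in unit tests, 1e5 in the acceptance checks) are the package's
working scales for stable tail estimates.

## Numerical choices and degenerate inputs

Quantiles: linear interpolation of order statistics everywhere. The `g -> 0`
branch switches at `|g| < 1e-8`. The numeric inverse targets
`|T(z) - x| <= tol * max(1, |x|)` with `tol = 1e-10`. Constant columns and
columns whose ASO scores have zero range raise a typed degenerate-distribution
condition and are skipped (and reported) at the table level; flagged cells
become `NA` rather than dropping rows, so one column's outliers never destroy
another column's data. Columns with fewer than 10 distinct numeric values
pass through untouched.

The uncorrected baseline (`aso_baseline_detect`) folds the ASO to a
nonnegative outlyingness (`|s|`), fits the two-percentile g-and-h estimator
on the probit scale, and removes scores beyond the model's single 99.3rd
percentile; folding is what reproduces the baseline's documented failure
signature (thin-tail outliers scoring below the cutoff under heavy skew,
TPR ~ 0.5, while clean symmetric data still loses ~0.7% from both tails).
Its anchor percentile defaults to `p = 0.99`, the variant whose clean-data
removal sits closest to 0.7%; the full 90–99 grid is available through the
`p` argument.

## Known limitations

* On strongly monotonic shapes the fitted `h` tail is conservative against
  the bounded range of probit scores: the model's 99.65% quantile lands near
  the empirical 99.86% point on Exp(1), so removal runs at roughly 0.3%
  rather than 0.7%. The grand-mean calibration across shapes remains within
  ±0.3 percentage points of 0.7%.
* Very distorted monotonic features (e.g. exponentials raised to large
  powers) produce lumpy ASO-probit scores and can be routed to the mixture
  branch by the transformed-sample dip pre-test; the procedure stays
  conservative there, but such shapes are at the edge of what the model
  family fits.
* The dip bootstrap resamples from a continuous CDF; for barely-continuous
  data (just above 60 unique values) the null is slightly liberal, absorbed
  by the 0.0001 floor.
* Exactly two mixture components; genuinely trimodal features are fitted by
  the two dominant modes.

## Reproducing the headline numbers

`scripts/acceptance.R` (repository root) regenerates every benchmark input
and recomputes: the cell-level TPR of a rank-based ASO detector under the
multivariate contamination scheme; the detector's mean removal percentage on
clean normal / lognormal / Tukey-gh samples (20 seeds × 100,000 points
each); and the uncorrected baseline's TPR under extreme skew and extreme
monotonic distortion. All randomness derives from its `--seed` argument.
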