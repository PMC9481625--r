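---
title: "Genic distribution modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genic distribution modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(alleleNiche)
```

## The scientific problem

Intraspecific variants can have climatic niches of their own. In the bank
vole, two haemoglobin variants — HbS and HbF, one amino-acid apart in the
β-globin subunit — segregate along a north–south climate gradient in
Britain, with HbF's redox-active cysteine conferring better tolerance of
the oxidative stress associated with warmer conditions. Genic
distribution modelling treats each allele as the modelled unit: fit a
presence/background niche model per allele, quantify how distinct the two
climatic niches are, and project where each allele would be favoured
under altered climates. This package implements that pipeline end to end,
together with a synthetic-data generator whose ground truth lets every
stage be validated quantitatively.

## The maximum-entropy model

Let $f(x) \in [0,1]^p$ be a feature expansion of the climate values at a
landscape cell $x$, and let the background be a sample (or the entirety)
of the study-area cells. The model is the Gibbs distribution
$q_\lambda(x) = e^{\lambda \cdot f(x)}/Z(\lambda)$ over background cells,
with $\lambda$ minimizing

$$\mathrm{obj}(\lambda) = -\frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
  \;+\; \ln Z(\lambda) \;+\; \sum_j \beta_j |\lambda_j|,$$

a convex objective whose stationarity conditions pin each feature's model
mean to within $\beta_j$ of its empirical presence mean. The per-feature
weights are $\beta_j = c \cdot w_{\mathrm{class}}(m) \cdot s_j/\sqrt{m}$,
where $c$ is the global regularization multiplier, $s_j$ the feature's
presence standard deviation, and $w_{\mathrm{class}}$ the published
per-class default weight (linear/quadratic/product interpolated on the
presence count from $\{(0,1),(10,1),(30,0.2),(100,0.05)\}$; hinge fixed at
$0.5$).

**Features.** Variables are min–max scaled on the pooled training data
(presences + background), so the training range doubles as the clamping
range for transfer. Classes: linear ($x$), quadratic ($x^2$), product
($x_u x_v$), and forward/reverse hinges
$\max(0,(x-k)/(1-k))$, $\max(0,(k-x)/k)$ at 8 evenly spaced interior
knots per variable (a desk-scale stand-in for MaxEnt's dense hinge grid;
the knot count is recorded in the model). Classes default to the
presence-count rule: $<10$ L, 10–14 LQ, 15–79 LQH, $\ge 80$ LQHP — both
allele sample sizes here (40 and 57) land in LQH.

**Optimizer.** Cyclic coordinate descent with soft-thresholding. Each
coordinate takes a damped Newton step on the smooth part (curvature =
model variance of the feature, floored at $10^{-8}$), soft-thresholded by
$\beta_j$, then guarded by a 1-d backtracking line check so the objective
sequence is non-increasing by construction. The primary stopping rule is
the KKT gap itself ($\le$ `kktTol`, default $10^{-7}$); an
objective-improvement stall below `tol` (default $10^{-5}$) is accepted
only when the KKT gap is also below `tol`, so a returned, converged model
always satisfies mean-matching to $\beta_j$ + `tol`. Hitting `maxIter`
(500) returns a result flagged unconverged, with a warning rather than an
error, since permutation-test replicates must be allowed to carry on.

**Output scales.** `raw` re-normalizes $e^{\lambda f}$ over whichever
prediction domain is supplied (it sums to 1 there); `cumulative` is the
total raw mass at or below a cell's raw value; `cloglog` is
$1 - \exp(-e^{H} \cdot e^{\lambda f(x)}/Z_{\mathrm{train}})$ with $H$ the
entropy of the fitted distribution over the *training* background. Using
the training normalizer makes cloglog independent of the prediction
domain's size — projecting the uniform model anywhere gives
$1 - e^{-1}$ — which is what makes replicate-mean cloglog surfaces
comparable across stacks.

**Model selection.** AICc over a grid of feature-class sets and
multipliers (default $\{0.5, 1, 2, 4\}$), with
$\ln L = \sum_i \ln \mathrm{raw}(x_i)$ normalized over the full landscape
and $K$ = nonzero coefficients; candidates with $n \le K+1$ are invalid.
Ties break by fewer active coefficients, then the smaller multiplier.
Because the original study did not report its winning classes or
multipliers, the tuning grid is a reconstruction and the per-candidate
table is always returned for inspection.

## Evaluation and variable selection

AUC uses the Mann–Whitney pair-counting form (ties count ½), so it is
invariant under monotone transforms of the scores. The partial-AUC ratio
restricts the ROC to sensitivity $\ge 1 - E$ (default $E = 0.05$),
integrates the curve over false-positive rate with the entry vertex
linearly interpolated, and divides by the chance diagonal's area over the
same region; presences are bootstrap-resampled (50% with replacement, 100
replicates) and the p-value is the fraction of ratios $\le 1$. Replicate
train/test splits draw `round(testFraction * n)` test indices uniformly
(default 25%; the source study did not state its subsampling percentage).

"Reiterative jackknife" variable selection is under-specified in the
available text, so the package uses a concrete deterministic
reconstruction: repeatedly fit, compute per-variable gain-alone and
gain-without (unregularized training gain, $\ln n_{bg}$ minus the NLL
part), drop the variable with the lowest gain-alone until `targetK`
remain, then enforce the collinearity filter — while any surviving pair
has $|r| > 0.8$ on background values, drop the member with lower
gain-alone. Every iteration's table is kept in the report so alternative
drop criteria can be compared after the fact. Pearson correlation is used
(the convention in this literature); gain-alone is the assumed drop
criterion since the original's choice among gain/AUC/contribution is not
stated.

## Niche overlap and its tests

Schoener's $D = 1 - \tfrac12\sum_i |p_i - q_i|$ on vectors normalized to
unit mass. In geographic space the vectors are suitability surfaces over
the shared mask; in environmental space they are model predictions at a
Latin-hypercube sample (default 10,000 points) of the hyper-rectangle of
pooled training ranges. Raw-scale scores are mandated for $D$: cloglog is
monotone but not linear in raw, and normalization must precede any
transform for $D$ to be well-defined on densities.

The identity test pools both alleles' occurrences, repartitions them
randomly into the original sizes, refits both models with the observed
(tuned) settings, and recomputes $D$, `nReps` times; divergence makes the
observed $D$ small relative to the scrambled-label null, so the p-value
is one-sided-lower, $(1 + \#\{D_{null} \le D_{obs}\})/(n+1)$. The
background-similarity test instead replaces one allele's presences with
uniform draws from that allele's available region (default: the whole
study mask) and is two-sided, $2\min(P_{lo}, P_{hi})$ capped at 1. Null
replicates reuse the observed models' settings rather than re-tuning
(standard practice, and two orders of magnitude cheaper); a failed
replicate fit is retried up to 3 times with a fresh draw. Dual-type sites
enter the pooling as two typed records, matching the occurrence-table
representation.

## Projection, thresholds, favourability

Transfer clamps scaled features into the training range and returns a
companion clamping mask of affected cells. Scenario ensembles are
averaged cell-wise (a cell masked in any member is masked in the mean).
Suitability classes use training-presence thresholds on the replicate-mean
cloglog surface: minimum (marginal), 5th and 10th nearest-rank percentiles
(moderate, high), the value at 1-based index $\lceil qn \rceil$ of the
sorted presence values — the omission-threshold convention, bit-exact and
order-statistic based, with inclusive lower bounds so the classes nest.
Relative favourability compares the two alleles' replicate-mean cloglog
surfaces cell by cell (the original does not state its comparison scale;
cloglog is the package default because the 0–1 scale is comparable across
models, and the choice is recorded in provenance). Exact ties — measure
zero on continuous surfaces — go deterministically to the first allele
and are tallied.

## The synthetic world

The generator emulates the study conditions at desk scale: standardized,
spatially autocorrelated climate layers (smoothed white noise; Gaussian
kernel, default sd 4 cells on a 110×100 grid at British latitudes),
pairwise correlation imposed exactly on designated layer pairs by
residualize-and-mix (default 0.3, mimicking the moderate collinearity of
bioclim variables), product-Gaussian niche truths
$s = \exp(-\sum_v (z_v - \mu_v)^2/2\sigma_v^2)$, and
suitability-proportional occurrence sampling without replacement at cell
centres. Defaults mirror the study's marginal structure: 40 presences for
the cold allele (ENV1 optimum $-1$ sd), 57 for the warm allele (optimum
$+1$ sd), breadth 1, and a future stack equal to the present plus a +2 sd
shift on the temperature-like layer — chosen so the warm allele's
favourability expansion is a designed, testable direction rather than a
fitted outcome. The Gaussian truth is deliberately recoverable by
quadratic features, matching the unimodal response-curve narrative of the
modelled system.

What the generator does *not* emulate: the real covariance structure of
WorldClim rasters, coastline geometry, sampling bias, or any
presence/abundance distinction (suitability-proportional sampling is a
modelling convenience). Passing tests on synthetic worlds therefore
demonstrate correctness of the machinery and qualitative behaviour —
niche recovery, calibrated tests, directional favourability flips — not
quantitative agreement with any real-raster analysis.

## Numerical choices and degenerate inputs

Haversine distances on a sphere of radius 6371 km (sub-0.5% vs geodesic,
immaterial at a 10-km thinning threshold), with a $10^{-9}$ km tolerance
on the inclusive threshold so exact-boundary pairs survive floating-point
rounding. Grids are cell-centre registered, row 1 north; point-in-cell
containment is half-open, $[{\rm west},{\rm east}) \times ({\rm south},
{\rm north}]$, stated once and used everywhere. Thinning is greedy in
input order (deterministic, standard) and per-allele, since shared sites
legitimately carry both types. Zero-variance variables are rejected at
feature construction with the variable named; a presence set whose
climate rows are all identical is rejected as degenerate at the raw-value
level (feature-level duplicates are allowed — a single binary feature is
a legitimate fit). Permutation p-values use the add-one correction so
they are valid (never zero) at finite replicate counts. All seeded
operations restore the caller's RNG state.

## Problem sizes used in validation

The shipped tests validate on: 110×100 grids with 10,000-cell backgrounds
for niche recovery (Pearson $r \ge 0.8$ between fitted cloglog and truth);
60×60 worlds with 600-cell backgrounds and 99 randomizations for the
overlap tests (20 exchangeable-null worlds for calibration, rejection
rate $\le$ 0.2 at $\alpha = 0.05$); and reduced replicate counts (4) for
the end-to-end pipeline reproducibility checks. These sizes were chosen
as the smallest at which the statistical behaviour is stable; all counts
scale up through the config (`defaultRunConfig()` carries the full-scale
defaults: 50 replicates, 100 randomizations, 10,000 background points).

## Known limitations

No categorical or threshold features, no sampling-bias grids, no
spatially structured (block) cross-validation, no raster
reprojection/resampling (inputs must be pre-aligned), and no ellipsoidal
geodesy. GeoTIFF I/O is not provided; rasters move as ESRI ASCII grids.
The environmental-space $D$ depends on the chosen variable ranges
(pooled training ranges by default); models extrapolated far outside
those ranges are clamped, which flattens responses at the range edges —
visible in the clamping masks that projections carry.
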