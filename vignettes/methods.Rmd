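---
title: "Methods: host-conditioned maximum-entropy distribution modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-conditioned maximum-entropy distribution modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasdm)
```

`parasdm` models the distribution of a holoparasitic plant through the
distributions of its host plants. This vignette is the package's own
account of the science: the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic tests do and do
not demonstrate.

## The two-stage cascade

A holoparasite cannot establish where its hosts are absent, however
favourable the climate. The workflow therefore runs in two stages:

1. **Hosts.** Each host plant is modelled independently from the
   environmental predictors (principal components of the raster stack;
   see below). The fitted habitat-suitability layer of every host — on
   the cloglog (0, 1) scale — becomes a predictor raster.
2. **Parasite.** The parasite is modelled with the host suitability
   layers as its covariates, using the identical tuning and selection
   machinery. Host suitabilities are treated as ordinary covariates with
   linear/quadratic/hinge features; no interactions among hosts are
   modelled.

The key assumptions are that hosts respond to the environment and not to
the parasite (commensal one-way coupling), that the hosts' *predicted*
suitability is an adequate proxy for their availability, and that
occurrence records are presence-only samples biased toward suitable
habitat but not otherwise structured.

Models are selected once, on current-scenario data, and transferred
frozen to every future scenario. Refitting per scenario is not possible —
future occurrences do not exist — and freezing both the models and the
PCA loadings keeps all scenarios in one comparable prediction space.

## Environmental preprocessing

Raw environmental stacks (about 30 layers in the motivating use case) are
strongly collinear, and collinearity learned in one time slice need not
hold in another. The package therefore reduces the stack by PCA on the
**correlation** matrix (layers mix °C, mm, %, and class codes, so each is
standardized first) computed over the jointly valid cells of the
*current* scenario only. Components are kept up to a cumulative explained
variance of `variance_target` (default 0.95). Means, standard deviations
and loadings are frozen and applied unchanged to future stacks. The
alternative — pooled current+future standardization — would leak future
information into the training representation.

Two caveats are documented rather than solved: categorical soil-texture
codes are treated as numeric, as upstream pipelines in this field do; and
the sign of each component is fixed by making its largest-magnitude
loading positive, which is a labelling convention, not substance.

Future climate comes as one stack per global climate model (GCM); the
package averages the GCM variants cellwise before projection, with
strict nodata propagation (a cell must be valid in every variant), so
scenario masks never drift apart.

## The maximum-entropy model

The core model is a from-scratch presence–background MaxEnt. Over a
background sample `B` of landscape cells, the model is the Gibbs
distribution `P(x) ∝ exp(λ·f(x))` maximizing entropy subject to soft
feature-mean constraints, fitted by maximizing the concave penalized
likelihood

```
L(λ) = mean_presence(λ·f) − log Σ_B exp(λ·f) − Σ_j β_j |λ_j|.
```

*Features.* Covariates are rescaled by their training bounds; the basis
holds linear `(x−min)/(max−min)`, quadratic (its square), and hinge
features — forward `max(0,(x−t)/(max−t))` and reverse
`max(0,(t−x)/(t−min))` at `k_h` equally spaced interior knots per
direction (default 20, configurable; examples in this package use 5 for
speed, which costs little at the smoothness scales of the synthetic
worlds). All features live in [0, 1].

*Penalties.* `β_j = rm · base(class, m) · s_j/√m`, where `m` is the
presence count, `s_j` the presence-sample SD of feature `j` (floored at
1e-4), and `base` interpolates the published MaxEnt default tables
(linear/quadratic: 1.0 at m≤10 down to 0.05 at m≥100; hinge: 0.5). The
regularization multiplier `rm` is a tuning dimension.

*Boundedness.* With background-only normalization the likelihood is
unbounded whenever some feature's presence mean lies outside the convex
hull of its background values — the presence–background analogue of
perfect separation, easily triggered by hinge features. The standard
remedy, which the pipeline follows, is to include the presence cells in
the background sample; `fit_maxent()` itself detects divergence and
raises an informative error rather than returning a runaway fit.

*Optimization.* The objective is convex but poorly conditioned on hinge
bases; plain and accelerated proximal-gradient methods stalled around
1e-2 in the projected-gradient norm. The package instead uses an
active-set scheme: coordinates violating the KKT conditions
(`|∇_j| > β_j` at zero) enter a working set with their descent sign, the
resulting sign-fixed smooth subproblem is solved by projected
quasi-Newton (L-BFGS-B on a non-negative reparametrization), coordinates
that hit zero leave the set, and the loop repeats until the minimal-norm
subgradient is below `tol` (default 1e-8, infinity norm). Each subsolve
can only lower the objective, so the outer objective trace is monotone —
a property the tests assert. Subproblem solutions below 1e-12 are
clamped to exact zero so a rounding residual at the bound cannot corrupt
the working signs.

*Outputs.* `raw` is the Gibbs density normalized over the training
background (it sums to 1 there — a conservation law the tests assert);
`cloglog`, the default for all downstream classing, is
`1 − exp(−e^H · raw)` with `H` the entropy of the fitted distribution;
`logistic` is `e^H·raw/(1+e^H·raw)`. Projection **clamps** covariates to
the training bounds: the model never extrapolates its response curves,
and extrapolation is instead *reported* by the ExDet diagnostics.

## Evaluation and model selection

*Spatial cross-validation.* Random k-fold splits leak information
through spatial autocorrelation. The package uses a hierarchical
checkerboard: two nested checkerboards at aggregation factors `a1` and
`a1·a2` (defaults 2, 2) define 4 folds via
`fold = 1 + g1 + 2·g2`, with `g1`, `g2` the fine and coarse parities of
the cell index. Presences and background partition by the same rule.

*Metrics.* AUC (tie-corrected Mann–Whitney), the omission rate at a
training-percentile threshold (default percentile 10, type-7 linear
interpolation — stated explicitly because omission values depend on the
quantile convention), and the Continuous Boyce Index.

*CBI.* The Boyce index asks whether the ratio of presence density to
landscape density increases with predicted suitability. The package
computes it on the **habitat-rank scale**: predictions are mapped through
the landscape's empirical CDF before windowing, which makes the index an
exact rank statistic — invariant under any strictly increasing transform
of the predictions, as a calibration measure should be. Windows are
narrow and numerous by default (201 windows of width 0.005 of the rank
range). The width matters: wide overlapping windows (e.g. 10% of the
range) contain only ~10 statistically independent blocks, so the Spearman
correlation of a *useless* model fluctuates with an SD near 0.33 and the
index loses its meaning as "0 = chance". With ~200 near-independent
narrow windows the null distribution concentrates (simulation: 99 of 100
uniform-presence replicates inside ±0.2).

The narrow windows trade power for calibration: with only a few dozen
evaluation presences — the typical size of a cross-validation fold —
most narrow windows are empty and the index is attenuated toward zero
for good and bad models alike. The cross-validation configuration
therefore evaluates folds with the classic wide-window convention
(101 windows of width 0.1), where only the *ranking* of candidate
settings matters, while `cbi()` itself defaults to the null-calibrated
narrow windows appropriate for interpreting the index's absolute value
on large evaluation sets. Both parameter pairs are configurable.

*Selection.* Candidates are the cross of feature-class combinations
{L, Q, H, LQ, LH, QH, LQH} and `rm ∈ {0.5, 1, 2, 4}`. The winner
maximizes mean CBI across folds; ties break toward lower mean omission,
then higher mean AUC, then candidate order. The winner is refit on all
presences before projection.

## Transfer diagnostics

*ExDet.* For each projection cell, NT1 sums the negative univariate
range exceedances against the reference sample (the model's training
rows); where NT1 = 0, NT2 is the squared Mahalanobis distance to the
reference mean scaled by the reference maximum, so NT2 > 1 flags novel
covariate *combinations* inside univariate ranges. Cells are classed
univariate / combinatorial / analogue; the classes partition the valid
cells. The most influential covariate (MIC) is the worst exceedance
(univariate cells) or the covariate whose omission most reduces NT2, by
exhaustive leave-one-out recomputation (combinatorial cells). A
near-singular reference covariance receives a ridge of
`1e-8·trace/p` on the diagonal, with a warning.

*%N.* The percentage of reference rows within an axis-aligned box of
half-width `radius_sd` reference SDs (default 1) on every covariate —
high %N means the cell sits in well-sampled covariate space.

*Reference space.* For the parasite model the diagnostics run in
host-suitability space (its training covariates); for host models, in PC
space. Both are supported; the parasite/host-space default reflects which
model's transfer is being diagnosed.

*Niche similarity.* Schoener's `D = 1 − ½Σ|p−q|` and Warren's
`I = 1 − ½Σ(√p−√q)²` between suitability surfaces normalized to
probability distributions over the joint valid mask. Both equal 1 exactly
when the normalized surfaces coincide; neither dominates the other in
general, so no ordering between them is asserted.

## Habitat classes, trends, and the reserve

Suitability is cut into four classes — inappropriate (ISH), low (LSH),
medium (MSH), highly suitable (HSH) — by Fisher–Jenks natural breaks: the
exact dynamic program minimizing within-class squared deviation,
vectorized over split points (O(k·n²) work). Above 1e5 cells the breaks
are fitted on a seeded uniform subsample of 10,000 (configurable); the DP
is exact on everything the tests compare against enumeration. Intervals
are right-closed (a value equal to a break falls in the lower class), and
future layers are always classified with the breaks fitted on the current
scenario, so per-class areas are comparable across scenarios.

Per class and scenario, the change ratio is
`r = (A_future − A_current)/A_current` with areas from exact spherical
cell geometry (`A = R²·Δλ·(sin φ_top − sin φ_bot)`, R = 6371.0088 km, the
IUGG mean radius). The maximum growth/reduction ratios (MGR/MRR) are the
extreme ratios across scenario×period keys. A (host, class) pair is
"shrinking" when its ratio is negative in at least half the keys *and*
its mean ratio is negative — an explicit operationalization of a
case-by-case judgement, configurable.

Hosts are screened by mean niche similarity I across scenarios
(threshold 0.9) and ranked by their share of univariate-MIC
attributions. The core reserve is, by default, the **intersection** of
the parasite's current MSH∪HSH with cells where some shrinking,
influential (host, class) pair matches the host's current class; a union
rule is available, since prose descriptions of such rules are genuinely
ambiguous between the two readings. An empty shrink set degrades to the
parasite habitat alone, with a warning.

## The synthetic world

Real occurrence and climate data are large, access-restricted, or both;
the generator provides a fully specified world with known truth:

- **Covariates:** `n_covariates` (default 30) layers driven by
  `n_latent` (default 8) independent latent fields — white noise smoothed
  by a Gaussian kernel (`smoothing_length` 5 cells), centred,
  orthogonalized and standardized. Each covariate loads mainly on one
  latent (assigned cyclically, as real bioclim/soil variables cluster
  into groups) plus 40% random cross-talk and independent measurement
  noise (SD 0.1). This makes the latent rank visible in a scree plot:
  correlation-matrix PCA at a 95% target recovers exactly 8 components,
  mirroring the 30-variable→8-component structure of the motivating
  data. The orthogonalization also makes covariate correlations follow
  the mixing geometry exactly (`cor ≈ cos θ` between mixing rows), which
  the tests exploit.
- **Futures:** per SSP-style scenario, latents shift along a fixed trend
  field by `trend_magnitude × period index`; each GCM variant adds
  latent noise of SD `gcm_noise_sd` (0.1). With zero GCM noise, variants
  are identical — a degenerate case the ensembling tests use.
- **Truth:** host `h` suitability is `plogis(α_h + w_h·latents)`, each
  host driven primarily by its own latent field plus a weaker secondary
  from the remaining pool (hosts sharing primary drivers would correlate
  so strongly that their niches could not be told apart — defeating the
  point of a known ground truth); parasite truth is
  `plogis(a + Σ v_h·host_h)` with configurable weights (default
  (3, 3, 1, 0, 0) over five hosts).
- **Occurrences:** `n_presence` (default 200) cells drawn without
  replacement with probability proportional to truth, jittered uniformly
  within the cell so that per-cell thinning is a real operation, not a
  no-op.

The default world is 120×100 cells — sized so the full pipeline runs in
minutes on one core. What passing tests show: the machinery recovers
planted monotone structure (host ranking by parasite-truth weight,
Spearman agreement with truth surfaces, latent rank). What they do not
show: robustness to sampling bias, to spatially structured detection
error, to non-monotone responses, or to real climate physics — none of
which the generator emulates.

## Numerical and interface choices

- Grid convention: WGS84 lon/lat, top-left origin, rows southward, cells
  addressed by centre, membership `[west, east) × (south, north]`.
- Duplicate occurrence records are detected after rounding coordinates
  to 6 decimals (≈0.11 m); thinning keeps the first record per cell in
  input order (deterministic).
- Rasters on disk are ESRI ASCII grids written at 17 significant digits
  (bit-exact round trips); stacks live in a directory with a JSON
  manifest. No GeoTIFF support: no georeferenced-raster reader is
  available to the package, and plain-text grids cover every pipeline
  need.
- Background: 10,000 cells sampled uniformly without replacement (all
  cells if fewer), seeded, plus the presence cells (see *Boundedness*).
- Model and PCA transforms serialize to JSON in full double precision.
- Configuration is a validated R list (`run_config()`), loadable from
  YAML; unknown keys are rejected by name. The examples and test
  pipelines use reduced settings (smaller candidate grids, `k_h = 5`,
  background 1000–2000, 50×40 worlds) — the package's own desk-scale
  defaults for illustration; every parameter scales up by configuration.
- Every stochastic step takes an explicit seed; pipeline results are
  bit-reproducible from the configuration.

## Known limitations

- Presence-only data cannot identify prevalence; cloglog values are
  relative suitabilities, and AUC on presence–background data is a
  ranking score, not a classification accuracy.
- Treating predicted host suitability as the parasite's covariates
  propagates stage-1 error into stage 2 with no uncertainty accounting;
  a poorly transferring host model contaminates the parasite projection
  (which is why the ExDet/%N diagnostics run in host-suitability space).
- The checkerboard partition assumes an isotropic, grid-aligned
  autocorrelation scale; `a1`, `a2` must be chosen with the species'
  range structure in mind.
- Jenks classes on a subsample are exact only for the subsample;
  class boundaries can shift by O(1/√n) relative to the full layer.
- The reserve rule is a deterministic set operation on classified maps;
  it ignores connectivity, dispersal, and land tenure.
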