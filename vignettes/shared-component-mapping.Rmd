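---
title: "Shared-component geostatistical mapping of childhood comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-component geostatistical mapping of childhood comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregmap)
```

## The scientific problem

Acute respiratory infection (ARI), diarrhoea and stunting co-occur in
children under five, both within children and — the ecological question
this package addresses — within places.  Cluster nutrition surveys
record, for each child nested in a household within a geolocated
enumeration cluster, binary indicators of the three conditions plus
child, household and environmental covariates.  `coregmap` estimates
the *shared* latent spatial risk of the three conditions: where their
residual spatial patterns coincide after measured covariates are
accounted for, and how confident one can be that the shared risk
exceeds a policy-relevant level.

## The model

For child $i$ in cluster $j$ with coordinates $s_j$ and condition
$k \in \{1,2,3\}$ (ordered ARI, diarrhoea, stunting),

$$y_{ijk} \sim \mathrm{Bernoulli}(p_{ijk}), \qquad
  \mathrm{logit}\, p_{ijk} = \eta_{ijk}
  = \alpha_k + x_{ij}'\beta_k + u_k(s_j),$$

with condition-specific intercepts $\alpha_k$ and covariate effects
$\beta_k$.  The spatial terms are linked through a triangular linear
model of coregionalization over three *independent* Matérn Gaussian
random fields $z_1, z_2, z_3$:

$$u_1 = z_1, \qquad
  u_2 = \lambda_1 z_1 + z_2, \qquad
  u_3 = \lambda_2 z_1 + \lambda_3 z_2 + z_3.$$

The copy coefficients $\lambda$ are unconstrained; $\lambda = 0$
decouples the conditions, and the implied cross-covariance between any
two composed fields is available in closed form
(`implied_cross_covariance()`), which anchors both the synthetic-data
generator and the sampler tests.  The triangular construction is
order-dependent; the condition order is configurable and documented in
`model_spec()`.

### Matérn fields and the range convention

Each component field has marginal standard deviation $\sigma$,
smoothness $\nu$ (default 1) and a *practical range* $\rho$: the
distance at which correlation falls to roughly 0.1, with
$\kappa = \sqrt{8\nu}/\rho$.  We state this prominently because range
conventions differ across software and the parameter is otherwise easy
to misread.  Distances are Euclidean in planar kilometres; tables
supplied in longitude/latitude are converted by a stated
equirectangular projection (`cluster_sites()`).

Two backends exist.  The **dense** backend (default) evaluates the
exact covariance and is used everywhere at desk scale (up to a few
thousand sites).  The **sparse GMRF/SPDE** backend
(`spde_precision()`) assembles the precision of the $\nu = 1$ field on
a regular grid with a lumped mass matrix and 5-point Laplacian, with
$\tau = 1/(\kappa\sigma\sqrt{4\pi})$ fixing the marginal variance; a
non-stationary variant takes per-node $\log\kappa$, $\log\tau$ affine
in node covariates (`nonstationary_params()`).  Natural boundaries
inflate variance near the edge, so grids are built with a two-range
extension (`spde_grid()`); the residual discretisation error is
quantified in the test suite (marginal variance within 10% at spacing
$\rho/8$, KL divergence below 0.01 per node on spaced site sets)
rather than hidden.  Mesh-sensitive quantities are validated against
the dense backend, not against any external mesh.

### Priors

Priors shrink toward the base model of no spatial effect and no
sharing:

* field standard deviation: penalised-complexity (exponential) prior
  with $P(\sigma > 1) = 0.01$;
* practical range: PC range prior
  $\pi(\rho) \propto \rho^{-2} e^{-\theta/\rho}$ with
  $P(\rho < 10\,\mathrm{km}) = 0.05$;
* copy coefficients: Gaussian shrinkage to $\lambda = 0$ with unit
  scale;
* intercepts and covariate effects: diffuse Gaussians (sd 10 and 5).

The PC-prior tail definitions are configurable (`default_priors()`,
overridable per `model_spec()`), since only the prior *families* are
fixed by the modelling tradition the package follows; all settings are
recorded in the fit object.

## Inference

The posterior is explored by MCMC rather than nested Laplace
approximations: a sampler whose target is the exact posterior gives a
reference against which closed-form oracles can be asserted.  One
sweep comprises

1. **elliptical slice sampling** of each whitened field vector $v_k$
   (the field is parameterised non-centred as
   $z_k = \sigma_k R_k^{\top} v_k$ with $R_k$ the Cholesky factor of
   the correlation matrix, so hyperparameter moves stay well behaved);
2. elliptical slice updates of $(\alpha_k, \beta_k)$ per condition and
   of $\lambda$ — all have Gaussian priors, so slice sampling applies
   with no tuning;
3. adaptive random-walk Metropolis on $\log\sigma_k$ (cheap: the
   realised field rescales) and $\log\rho_k$ (one new Cholesky per
   proposal), with Robbins–Monro adaptation to 0.44 acceptance during
   warmup;
4. a centred ("ASIS"-style) slice update of $\sigma_k$ holding the
   realised field fixed, then re-whitening — interweaving the two
   parameterisations breaks the $\sigma$–field coupling that otherwise
   dominates the autocorrelation time;
5. a level-interweaving move that shifts a field's constant level into
   the intercepts (all linear predictors unchanged, acceptance on the
   priors only), which decouples $\alpha_k$ from the field mean.

Steps 1–2 are repeated `n_inner` times per sweep (default 3) because
the hyperparameter moves dominate the cost.  Without child-level
covariates the Bernoulli likelihood is aggregated to cluster-level
binomial sufficient statistics, making a likelihood evaluation $O(J)$
in the number of clusters.  A fast uniform-grid interpolant of the
$\nu = 1$ Matérn correlation (max absolute error $< 10^{-6}$) is used
inside the sampler's inner loop only; `matern_cov()` itself is exact.

Initialisation: intercepts at empirical logit prevalences, effects and
fields at zero, hyperparameters at prior medians.  Convergence is
reported, never silently passed: split-$\hat R$ and effective sample
size for every scalar parameter live in the fit's `diagnostics`, and a
fit warns when any $\hat R > 1.05$.  Separate per-condition models
(`fit_separate()`) use the same machinery with $\lambda \equiv 0$ and
per-condition fields.

What the sampler is tested against: brute-force quadrature of the
exact posterior on a tiny instance with clamped fields; 95% credible
interval coverage of $\lambda$, $\alpha$ and $\log\sigma$ of at least
85% over twenty simulated surveys of 150 clusters × 30 children
(weakly identified range parameters are deliberately excluded from
this bar — with ~10² clusters $\rho$ is poorly determined, a known
property of geostatistical logistic models, and its posterior is
dominated by the prior tails).

## Model assessment

`waic()`, `dic()`, `cpo()` and `pit()` operate on the per-observation
log-likelihood draws stored in the fit.  Definitions follow the
standard draw-based estimators; two choices deserve note.  The DIC
plug-in deviance is evaluated at the posterior mean of the *linear
predictor* (the latent-model convention), not of raw hyperparameters.
CPO uses the harmonic-mean leave-one-out identity, retained for
comparability with the toolchain tradition this package follows, but
carries an instability flag when a single importance weight dominates;
the summary reports both $\sum_i -\log \mathrm{CPO}_i$ (the
cross-validated score) and the plain $\sum_i \mathrm{CPO}_i$, clearly
labelled, because single-number "CPO" columns in published comparisons
are ambiguous between the two.  For binary data the randomised PIT
$P(Y < y_i) + v\,P(Y = y_i)$, $v \sim U(0,1)$, is uniform under
calibration and is the default; the non-randomised $P(Y \le y_i)$
variant is available.  All criteria are checked against exact
Beta–Bernoulli conjugate calculations and additivity/reordering
properties in the test suite.  `compare_models()` assembles the
joint-versus-separate table per condition and in total, stating that
lower DIC/WAIC is better.

## Excursion mapping

`predict_fields()` draws each component field at grid points from its
exact Gaussian conditional given the site values, per posterior draw
(kriging mean plus conditional-covariance draw under the dense
backend), then composes the shared fields with that draw's $\lambda$.
`marginal_exceedance()` maps per-cell posterior probabilities that a
field exceeds a level (default 0.2 on the latent log-odds scale — the
level's scale is an explicit argument since thresholds on latent,
exponentiated or probability scales differ materially).
`simultaneous_excursion()` forms a *simultaneous* excursion set: cells
are ordered by decreasing marginal exceedance probability (a
one-parameter nested family) and the set is the largest prefix whose
joint exceedance probability across draws still clears $1-\alpha$.
This sample-based construction mirrors the parametric-family idea of
the Gaussian quantile-correction method but works directly on MCMC
draws; exhaustive-enumeration oracles on small problems pin it down in
the tests.  Surfaces export as ESRI ASCII grids with value-exact round
trips; GeoTIFF is intentionally not emitted (no raster engine among
the package's dependencies) and requesting it errors clearly.

## The synthetic-data generator

Because the survey microdata this class of analysis uses are not
public, the generator (`simulate_survey()`) is first-class, tested
code that runs the model forward and records complete truth.  The
`"somalia-like"` preset emulates the study conditions: 1,066 clusters
with 30–70 children each (children nested in households of mean 2.3
children) in an 800 × 1,600 km domain; marginal prevalences
calibrated to 17%/26%/31%; household size and number of under-fives
increasing risk while food-group access, rainfall, vegetation and
urbanisation decrease it; rainfall and vegetation declining toward the
south so that risk concentrates in a southern band; and copy
coefficients $\lambda = (0.85, 0.45, 0.80)$ with field parameters
$\sigma = (0.75, 0.45, 0.50)$, $\rho = (200, 150, 150)$ km calibrated
once so cluster-level prevalence correlations fall in the 0.3–0.7 band
with the ARI–stunting pair weakest — the qualitative pattern
(0.66/0.63/0.37 ordering) reported for the real surveys.  The
intercepts $(-1.60, -0.97, -0.65)$ come from a one-off iterative
calibration at full scenario size; realised national prevalence still
moves a few points across seeds because the leading field's range is a
sizeable fraction of the domain — as it would in reality.

Deliberate simplifications, hence what passing tests do *not* show
about real data: cluster locations are uniform rather than
population-weighted; covariates are stationary Gaussian/Bernoulli
rather than seasonal rasters; the household intercept defaults to zero
variance (the fitted model has no household term, so the default
generator stays inside the model class — a household effect is a
configurable knob, and the within-cluster design effect is likewise a
knob rather than an asserted value); and no survey weighting exists
anywhere (the emulated analysis is unweighted).  `"desk-small"` (120
clusters × 20 children) keeps test suites fast;
`"null-independence"` sets $\lambda = 0$.

## Numerical choices and degenerate inputs

* Bernoulli log-likelihood via branch-free
  $\max(\eta,0) + \log(1+e^{-|\eta|})$; exact for $|\eta|$ up to
  overflow.
* Correlation factorisations carry a $10^{-8}$ diagonal jitter;
  coincident sites beyond jitter tolerance are an error with a clear
  message (the generator jitters-and-warns once before giving up).
* Conditional-simulation covariances are eigendecomposed with negative
  eigenvalues clamped at zero, so a prediction point coinciding with a
  data site reproduces the site draw to factorisation tolerance.
* Degenerate association-test margins (a condition all 0 or all 1)
  yield statistic 0 with a warning; zero-variance cluster proportions
  make the affected correlation `NA` with a warning, never a silent 0.
* Percentages round half away from zero, matching the printed style of
  survey reports.
* Problem sizes in the test suite — 150 × 30 coverage replicates,
  120 × 15 comparison replicates, 5,000-replicate covariance oracles —
  were chosen as the smallest sizes at which the checked properties
  are decisively identified at desk scale.
* "Strong sharing" in the joint-versus-separate comparison means the
  shared components dominate the spatial variance (leading field
  $\sigma = 0.9$ against idiosyncratic $\sigma = 0.35$, copy
  coefficients $(0.8, 0.6, 0.5)$).  When shared and idiosyncratic
  variances are comparable, the predictive gap between joint and
  separate models at desk scale is genuinely within WAIC noise — the
  borrowing advantage, not the factorisation, is what the comparison
  detects.

## Known limitations

The GMRF backend supports $\nu = 1$ on regular grids only; arbitrary
triangulations are out of scope at desk scale.  Harmonic-mean CPO is
noisy for influential observations (flagged, not smoothed).  The range
parameters are weakly identified at a few hundred clusters and their
coverage is not asserted.  The reported odds-ratio-scale summaries for
$\lambda$ are one of several defensible functionals of the shared
effects; `summarise_fit()` exposes the exponentiated-draw summaries
without asserting that any single one matches a given published
number.  Fitting all three conditions at the full 73,778-child scale
is supported but not exercised in the test suite.
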