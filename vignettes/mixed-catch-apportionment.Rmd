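---
title: "Splitting mixed mackerel catches: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting mixed mackerel catches: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `zoibcatch`: the
zero-one inflated beta (ZOIB) composition model, the additive-model and
centroid stages built on its output, the synthetic-data generator that
stands in for proprietary logbook and ocean-reanalysis data, and the
numerical choices made where the design was genuinely open.

## 1. The composition model

### Distribution

Daily species proportions from mixed catches live on the closed interval
`[0, 1]` and contain genuine point masses at both ends: on some
vessel-days the school is effectively single-species.  A Beta regression
alone cannot represent those atoms; discarding them would throw away the
most informative observations.  The ZOIB distribution keeps all three
parts:

* with probability `zoi`, the day is a boundary day; it is pure blue
  mackerel with conditional probability `coi` (so mass `zoi * coi` at 1
  and `zoi * (1 - coi)` at 0);
* otherwise the proportion follows a Beta distribution in the
  mean–precision parameterization, `Beta(mu * phi, (1 - mu) * phi)`.

`dzoib()`, `rzoib()` and `zoib_mean()` implement the density, sampler and
mean `zoi*coi + (1 - zoi)*mu`.  The density's atoms plus the interior
integral sum to one; the test suite verifies this to `1e-6` over a
parameter grid.

### Regression structure

All four parameters are regressed on the same environmental covariates:
logit links for `mu`, `zoi` and `coi`, a log link for `phi`.  The links
are the conventional ZOIB choices; putting covariates in the inflation
components as well as the Beta component means the same predictors
explain both extreme and intermediate compositions.  Covariates are
standardized (zero mean, unit standard deviation) inside `zoib()` —
without a common scale, a shared shrinkage prior on the slopes would be
meaningless.

A Gaussian spatial random effect `u ~ N(0, sigma_u^2)` enters the mean
predictor, indexed by spatial block (1°×1° grid cells of record position
by default, configurable).  Entering `mu` only — rather than all four
predictors — is a deliberate simplification: the mean composition is
where residual spatial autocorrelation is most plausible and most
damaging, and a four-fold random effect would be poorly identified at
realistic event counts.

### Priors

* Non-intercept slopes: Laplace (double-exponential) with scale
  `prior_scale` (default 1), a weakly informative shrinkage prior against
  overfitting.  Intercepts are unpenalized.
* `sigma_u`: lognormal with median 0.3 and log-scale standard deviation
  1.  Two considerations fix this form.  First, 0.3 on the logit scale is
  a moderate block-to-block heterogeneity — odds shifts of ±35% — which
  is what one expects of residual spatial structure after six
  environmental covariates.  Second, and decisively, the *joint* mode of
  `(u, sigma_u)` under any prior with non-vanishing density at zero
  collapses to `sigma_u = 0`: the `B log(sigma)` term of the random-effect
  density diverges as `sigma -> 0` faster than any fixed penalty grows
  once the number of blocks `B` is large.  The MAP estimator therefore
  does not try to estimate `sigma_u` at all: it profiles `u` with
  `sigma_u` held at the prior median.  The MCMC sampler, which integrates
  over `u`, samples `sigma_u` from its proper marginal posterior.

### Estimation

`method = "map"` minimizes the negative log posterior by BFGS with
analytic gradients (checked against finite differences in the tests).
The Laplace penalty is smoothed as `sqrt(b^2 + 1e-16)` so the objective
is differentiable at zero; the smoothing constant is far below any
meaningful coefficient magnitude.  Standard errors come from the observed
information (inverse Hessian) at the mode.

`method = "mcmc"` runs the conventional four chains of 4000 iterations
with the first 2000 discarded, targeting the posterior with the *exact*
Laplace prior.  The kernel is block-wise adaptive random-walk Metropolis:

* blocks are the four coefficient vectors plus a spatial block holding
  `u`, `log sigma_u` *and the mean intercept* — the intercept trades off
  almost one-for-one against the random-effect level, and proposals that
  know about that ridge are the difference between R-hat ≈ 1.03 and
  R-hat ≈ 1.07 at realistic sizes;
* proposals start from the inverse-Hessian sub-blocks of the MAP fit and
  are re-shaped during burn-in from the chain history, with each block's
  step scale tuned toward an acceptance rate of 0.3; the spatial block,
  the slowest subspace, receives four proposals per iteration;
* all adaptation freezes at the end of burn-in, so retained draws come
  from a fixed kernel;
* chains initialize at the MAP estimate jittered by one standard error,
  and every run is reproducible from its seed.

Convergence is assessed by the split Gelman–Rubin statistic (`rhat()`):
each chain's retained draws are halved and `sqrt(V/W)` computed from the
within-half and between-half variances, with the conventional gate
`max R-hat <= 1.05`.  Parameters held fixed (see below) have zero
variance and are flagged `NA` rather than reported as converged.

### Degenerate responses

If the response contains no interior values, the Beta component is
unidentifiable: its coefficients are held at empirical-logit intercepts,
flagged in `summary()`, and the fit proceeds on the inflation components.
Symmetrically, with no boundary values `zoi`/`coi` are held fixed, and
with one-sided boundaries (only zeros or only ones) `coi` is.  This
matters in practice for cross-validation refits on small folds.

### Model checking

`posterior_predictive()` draws parameter vectors from the posterior (or
from the Gaussian approximation at the mode for MAP fits), simulates a
full replicated response per draw — 100 replicates by convention — and
compares the observed fraction of exact zeros, fraction of exact ones,
mean, and interior deciles against the replicated envelope.

`kfold_cv()` scores held-out predictions by RMSE, MAE and R² (the
`fit_metrics()` formulas; R² may be negative and is flagged undefined for
constant observations).  Folds are formed either by record or — the
default — by spatial block, so that entire blocks are held out together;
blocked folds are the honest choice when records are spatially
autocorrelated.  Refits use the MAP estimator for speed; `method =
"mcmc"` refits are available.

### Apportionment

`split_catch()` multiplies each record's mixed catch by the predicted
blue proportion; the chub share is the exact arithmetic remainder, so the
two species reconstruct the recorded total (to within one unit in the
last place — a floating-point sum of a value and its remainder can differ
from the original by one ulp).  Per-set values divide by the day's haul
count, giving the effort-standardized response of the next stage.

## 2. Environmental covariates

Rasters are daily fields of SST, chlorophyll-a (on a coarser native
grid), salinity, sea-surface height, the two current components and
mixed-layer depth.  `regrid()` aligns the chlorophyll grid with the
physics grid by nearest-neighbour resampling; `match_env()` joins each
record to the same-day value at the nearest cell centre.  Distances are
measured in degree space, not great-circle: at the latitudes and cell
sizes involved the selected cell is almost always identical, and
grid-index matching is what raster tooling does in practice.  Ties break
toward the lower latitude index, then the lower longitude index.  Records
whose nearest cell is missing for any variable are dropped and counted —
silently imputing the nearest *valid* cell would smear coastal gradients.

`correlation_filter()` applies the conventional multicollinearity screen:
while any covariate pair has `|r| >= 0.7`, remove the lower-priority
member of the worst-offending pair.  The filter is iterative greedy
rather than single-pass so its behaviour is defined for any correlation
structure, and its result is invariant to row order.  The default
priority (SST > Chla > SSS > MLD > UO > VO > SSH) encodes the ecological
argument that salinity separates the two species' niches while
sea-surface height is the most substitutable of the candidates; with the
generator's default correlation structure (SSS–SSH at 0.72) exactly SSH
is removed.  Constant columns get a warning and zero correlations.

## 3. Environmental response curves

The additive model regresses `ln(catch per set + 1)` — the log-plus-one
keeps zero-catch records — on one penalized spline per retained
covariate:

* cubic B-splines of basis dimension `k = 10` on *unclamped, uniformly
  spaced* knots extending past the data range (the P-spline convention).
  Uniform unclamped knots make the Greville abscissae linear in knot
  index, so the null space of the second-difference coefficient penalty
  is exactly the constant and linear functions: infinite smoothing
  shrinks a term to a straight line, and a noise-free linear signal
  yields one effective degree of freedom.  `k = 10` gives reference
  degrees of freedom up to `k - 1 = 9`, the conventional default;
* each smooth carries a sum-to-zero constraint over the observed
  covariate values (absorbed by a QR reparameterization), identifying the
  intercept;
* smoothing parameters are chosen by generalized cross-validation,
  `GCV = n RSS / (n - edf)^2`, via coordinate descent over a log-spaced
  grid with a golden-section refinement.  GCV was preferred to REML for
  determinism and implementation transparency; it is documented as
  approximate relative to REML-based tooling.  Near-ties in the GCV score
  resolve toward the *larger* smoothing parameter: for exactly
  representable signals every candidate interpolates and the score
  differences are pure rounding noise, and the smooth limit is the
  defensible representative of that equivalence class;
* per-term effective degrees of freedom are the trace of the term's block
  of `(X'X + S)^{-1} X'X`; the reference degrees of freedom use the
  `2A - A^2` form of the same matrix, which always lies between the edf
  and `k - 1`;
* p-values are Wald-type tests of the term's coefficients against zero
  using the frequentist covariance, referred to an F distribution.  They
  are approximate — penalized estimates are biased toward zero, so these
  p-values are conservative for heavily smoothed terms — and are labelled
  as such;
* confidence bands use the Bayesian covariance `sigma^2 (X'X + S)^{-1}`,
  the standard choice for smooth intervals.

`optimal_range()` operationalizes the "narrowest confidence band" rule
for optimal environmental ranges: grid points whose band width falls in
the narrowest 20% (configurable; 0 selects the single narrowest point)
are selected, and the largest contiguous run is returned, ties resolving
toward the run containing the curve maximum.  A constant-width band
returns the whole grid flagged non-informative rather than an arbitrary
interval.

## 4. Centroid dynamics

Annual centres of gravity are plain weighted arithmetic means of
longitude and latitude, weighted by per-record species proportion.  Raw
proportions, not catch-weighted proportions, are the default weight —
the two readings are both defensible; weighting by `p` alone answers
"where is the species' share of the fishery" without letting a few very
large catches dominate, and `centroid_weighting = "catch"` provides the
alternative.  Degree-space averaging (no great-circle correction) is the
standard centre-of-gravity definition at these scales; distances
*between* centroids, by contrast, are haversine great-circle distances in
km, since a physical separation is being reported.

Uncertainty comes from a bootstrap that resamples whole records
(position + weight pairs) with replacement — the record is the natural
exchangeable unit — with percentile intervals, 1000 resamples and the
95% level by default, and capped redraws of degenerate all-zero-weight
resamples.  Years with fewer than 10 records are flagged, not silently
included.  Trends are ordinary least squares of centroid coordinate on
year, reported with R², the two-sided slope p-value, and two residual
normality diagnostics: the Jarque–Bera moment test and the
D'Agostino–Pearson omnibus K² (implemented from the standard transforms;
both verified against reference implementations to 1e-8).  The omnibus
transform is undefined below n = 8 and both tests reject constant input.

## 5. The synthetic-data generator

Real logbooks of this kind are proprietary and the matching reanalysis
extractions are bulky, so every stage runs against a seeded generator
whose ground truth is known.

What it emulates:

* **Fields.**  Smooth daily rasters built from low-order deterministic
  structure (latitudinal gradients, seasonal cycles) plus
  coarse-grid Gaussian noise bilinearly interpolated to the target grid.
  SST carries both a gradient and a seasonal cycle; chlorophyll lives on
  its own coarser grid (0.25° against 0.083°); sea-surface height is an
  affine function of salinity plus an independent field of identical
  spatial structure, orthogonalized in-sample so the field-wide Pearson
  correlation equals the configured target (0.72 by default) exactly.
  Smoothness is not incidental: the spline stage's recovery tests need
  differentiable response surfaces.
* **Fleet.**  Record positions are Gaussian around a population centre
  that moves by `(drift_lon_per_year, drift_lat_per_year)` annually —
  0.55°E and 0.3°N by default, the magnitude of the decadal shift this
  kind of analysis reports.  Catches are log-normal with an environmental
  component on the log scale (warmer, greener water raises expected
  catch), so catch per set carries a recoverable habitat signal; haul
  counts are `1 + Poisson(1)`.
* **Composition.**  Each record's latent proportion is drawn from the
  ZOIB regression truth evaluated at covariates standardized by fixed
  record-level constants.  The default truth gives the environment strong
  control of composition (held-out R² near 0.5 in the bundled
  end-to-end run), with boundary days at a ~10% base rate.  Boundary
  states are generated before any observation noise, so the inflation
  structure is identifiable.
* **Sampling events.**  A random subset of records is observed by
  counting `n_individuals` fish (1000 by default, the magnitude a
  credible identification protocol requires); the blue count is binomial
  in the latent proportion, which preserves latent boundary days as
  counts of exactly 0 or `n`.

Two design points deserve emphasis:

* **The habitat moves with the population.**  The latent proportion
  process is evaluated at *drift-corrected* positions.  If instead the
  environmental response stayed geographically fixed while positions
  drifted, the proportion-weighted centroid would acquire a
  time-varying offset and the generating drift would not be the expected
  value of the recovered trend — the recovery test would be checking a
  biased estimand.  In the drift-corrected frame the weighted centroid
  moves at exactly the configured rate in expectation.
* **Determinism is path-independent.**  All record-level randomness is
  drawn as uniforms in a dedicated substream before any field is
  evaluated, then transformed deterministically (quantile transforms for
  the Beta and log-normal draws).  Generating fields on the fly or
  passing pre-built ones therefore yields bit-identical logbooks, and
  each generator can be re-run independently from the same master seed.

What it does **not** emulate: vessel behaviour and effort allocation,
gear selectivity, bathymetry and real current systems, eddies or fronts,
observation error in positions, inter-annual environmental trends
(warming), or spatial clustering of sampling effort beyond the Gaussian
cloud.  Consequently, passing tests demonstrate that the estimators
recover the truth of *this* data-generating process at realistic sizes
and noise levels — not that the pipeline is robust to fleet-behaviour
confounding or climate-trend covariate drift in real logbooks.

## 6. Problem sizes and numerical choices

The bundled tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is genuinely informative:
MCMC convergence on n = 1000 with three covariates and nine spatial
blocks; coefficient coverage over 20 replicates of n = 2000; spline
recovery at n = 2000 with noise standard deviation 0.1; drift recovery
over 20 replicates of a 10-year, 150-records-per-year fleet; the
end-to-end run on a 10°×10° domain with 2000 records.  Other numerical
choices collected in one place:

* Laplace-penalty smoothing constant `1e-8` (on the coefficient scale)
  in the MAP objective; the MCMC target uses the exact prior.
* Optimizer: BFGS, relative tolerance `1e-12`, up to three restarts;
  non-convergence raises an error carrying the best-so-far state.
* Ill-conditioned observed information falls back to an
  eigenvalue-thresholded pseudo-inverse.
* Nearest-neighbour ties: lower index, each axis independently.
* GCV near-tie tolerance `1e-7` relative, resolving toward smoothness.
* Bootstrap degenerate-resample retries capped at 100.

## 7. Known limitations

* Two species only; no multinomial extension for three-way mixtures.
* No temporal random effects and no WAIC/LOO model comparison.
* The MAP estimator does not produce a data-driven `sigma_u`; use MCMC
  when the random-effect scale is itself of interest.
* GCV smoothing and Wald-type smooth-term p-values are approximations;
  they will not numerically match REML-based tooling, although fitted
  curves agree closely (the test suite cross-checks curves and deviance
  explained against an independent penalized-spline implementation).
* Sampling-event binomial error is not propagated into the composition
  model's likelihood; with 1000 individuals per event it is negligible
  next to day-to-day compositional variance.
* The centroid bootstrap treats records as exchangeable within a year;
  spatially clustered fleets violate this mildly, and the intervals
  should be read accordingly.
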