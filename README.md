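# zoibcatch

Purse-seine fleets targeting blue mackerel (*Scomber australasicus*) and
chub mackerel (*Scomber japonicus*) in the Northwest Pacific land the two
species as a single mixed catch: logbooks record where, when and how much
was caught, but not which species.  Species composition is only known at a
subset of sampling events where a crew identifies and counts individuals.
`zoibcatch` reconstructs species-specific abundance from such data: it
regresses observed species proportions on environmental covariates, uses
the fitted model to apportion every mixed record, and then characterizes
each species' environmental niche and its distributional drift.  It is
aimed at fisheries scientists working with mixed-catch logbooks and
gridded ocean reanalysis fields.

## The model

The daily proportion of blue mackerel `y ∈ [0, 1]` frequently takes the
exact values 0 and 1 (single-species days), so it is modelled with a
zero-one inflated beta (ZOIB) distribution:

    y = 1   with probability zoi · coi
    y = 0   with probability zoi · (1 − coi)
    y ~ Beta(μφ, (1 − μ)φ)   otherwise,

where `μ` is the Beta mean, `φ` the precision, `zoi` the probability of a
boundary (single-species) day and `coi` the conditional probability that
the boundary is pure blue mackerel.  All four quantities are regressed on
standardized environmental covariates (logit links for `μ`, `zoi`, `coi`;
log link for `φ`), with a Gaussian spatial random effect on the mean
predictor and Laplace priors on the slopes.  The expected proportion

    E(y | x) = zoi·coi + (1 − zoi)·μ

apportions each mixed record into `blue_kg = p·mixed` and
`chub_kg = mixed − blue_kg`.

Around this core the package provides

* **Covariate preparation** — nearest-neighbour regridding and record
  matching of daily rasters (SST, chlorophyll-a, salinity, sea-surface
  height, currents, mixed-layer depth), and an iterative pairwise Pearson
  screen that removes the lower-priority member of any pair with
  `|r| ≥ 0.7` (`regrid()`, `match_env()`, `correlation_filter()`).
* **Inference** — penalized maximum a posteriori with analytic gradients,
  and a seedable adaptive block-wise Metropolis sampler (4 chains × 4000
  iterations, 2000 burn-in by default) with split R-hat diagnostics,
  posterior predictive checks, and k-fold / spatially blocked
  cross-validation scored by RMSE, MAE and R² (`zoib()`, `rhat()`,
  `posterior_predictive()`, `kfold_cv()`, `fit_metrics()`).
* **Response curves** — a Gaussian additive model of `ln(catch/set + 1)`
  on penalized cubic B-spline smooths with GCV-selected smoothing,
  per-term effective degrees of freedom, approximate p-values and
  narrowest-confidence-band optimal ranges (`fit_additive()`,
  `partial_effect()`, `optimal_range()`).
* **Distribution drift** — annual abundance-weighted centroids (weighted
  mean longitude/latitude), bootstrap confidence intervals, OLS trends
  with Jarque–Bera and D'Agostino–Pearson omnibus residual diagnostics,
  and the inter-species centroid distance series
  (`centroid_series()`, `ols_trend()`, `centroid_distance_series()`).
* **Synthetic data** — a seeded generator for logbooks, sampling events
  and environmental rasters with known ground truth, including a
  configurable SSS–SSH correlation (default 0.72) and a configurable
  north-eastward population drift (`sim_config()`, `generate_logbook()`).
* **Orchestration** — `run_pipeline()` runs
  simulate → match → filter → fit → split → gam → centroids with content
  hashing, so unchanged stages are skipped on re-runs.

## Worked example

Simulate a decade of mixed-catch records whose population centre drifts
north-east at 0.3°/yr and 0.55°/yr, fit the composition model, apportion
the catches and recover the drift:

```r
library(zoibcatch)

cfg <- sim_config(
  spatial_domain = list(lon = c(150, 160), lat = c(33, 43)),
  start_center = c(lon = 153, lat = 37), spread = c(lon = 1.5, lat = 1.2),
  n_records_per_year = 200, n_days_per_year = 8, seed = 42)
fields  <- generate_env_fields(cfg)
logbook <- generate_logbook(cfg, fields)
events  <- generate_sampling_events(logbook, n_individuals = 1000,
                                    subsample_fraction = 0.5, seed = 43)

matched <- match_env(events, fields)$matched
screen  <- correlation_filter(matched,
             c("sst", "chla", "sss", "ssh", "uo", "vo", "mld"))
matched$block <- with(matched, paste(floor(lon), floor(lat), sep = "_"))

fit <- zoib(proportion_blue ~ sst + chla + sss + uo + vo + mld,
            matched, block = "block", seed = 44)
summary(fit)
```

```
Zero-one inflated beta regression (map)
n = 1000 rows; 15 exact zeros, 55 exact ones

                  Estimate  Std.Error       z Pr(>|z|)
mu:(Intercept)   9.345e-01  5.122e-02  18.244  < 2e-16 ***
mu:sst           1.156e+00  3.985e-02  29.010  < 2e-16 ***
mu:chla          2.457e-01  3.173e-02   7.745 9.53e-15 ***
...
sigma_u = 0.3 over 76 spatial blocks
```

The mean-predictor slopes are on standardized covariate scales: the blue
share rises steeply with temperature and chlorophyll and (further down
the table) falls with salinity, as generated.  Apportioning the logbook
and tracking the blue-mackerel centroid:

```r
mlog <- match_env(logbook, fields)$matched
mlog$block <- with(mlog, paste(floor(lon), floor(lat), sep = "_"))
split <- split_catch(mlog, predict(fit, mlog, block = "block"))
head(split[c("date", "mixed_catch_kg", "p_blue", "blue_kg", "chub_kg")], 3)
#>         date mixed_catch_kg    p_blue  blue_kg  chub_kg
#> 1 2014-10-31       3408.890 0.6680887 2277.441 1131.449
#> 2 2014-10-31      14325.873 0.5563581 7970.316 6355.557
#> 3 2014-10-31       3510.912 0.6981823 2451.256 1059.656

cs <- centroid_series(split, weight = "p_blue", B = 500, seed = 45)
ols_trend(cs$year, cs$lat)
#> OLS trend: slope = 0.3155 per year (95% CI 0.2903 to 0.3406 )
#> R2 = 0.991  slope p = 2.22e-09
#> residual normality: Omnibus p = 0.725  Jarque-Bera p = 0.852
```

The recovered northward trend (0.316°/yr, CI covering the generating
0.3°/yr) comes with residual diagnostics supporting the linear model.
Totals are conserved: `blue_kg + chub_kg` reconstructs each record's
mixed catch.

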