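# migcast

Forecasting nightly vertical profiles of nocturnal bird migration from
weather-radar observations and numerical weather data.

## The problem

Weather radars quantify nocturnal bird migration as vertical density
profiles (individuals km⁻³ in 250 m bins, 0–3000 m above ground). The
seasonal phenology of migration is well known; what operational users
(wind-farm curtailment, lights-out programs) need is the night-to-night
fluctuation around it, which is driven by weather — local wind, rain and
clouds at departure time, but also the synoptic weather systems of the
previous days that make birds accumulate and depart in pulses.

migcast implements a de-trended forecasting pipeline:

1. **Preprocessing** — hourly averaging of sub-nightly profiles, a
   minimum-5-bin completeness filter, interpolation to the standard 13-level
   grid, reflectivity→density conversion (RCS 11 cm² per bird),
   `log10(x+1)` transform, and insect-event exclusion by a BIC-gated
   Gaussian mixture on airspeed.
2. **Dimensionality reduction** — functional PCA of bird and local-weather
   vertical profiles (2 components each; weighted discretized PCA,
   trapezoid quadrature), and cos-latitude-weighted EOFs of synoptic
   anomaly fields on a 0.5° grid (4 modes per variable).
3. **De-trending** — circular day-of-year climatologies (Gaussian kernel,
   bandwidth 15 d, local-linear mean); bird-PC scores become standardized
   anomalies `z = (s − μ_d)/σ_d`, weather scores become anomalies.
4. **Forecasting** — gradient-boosted trees (squared error, leaf-wise
   growth, native missing handling) on a 117-predictor design: radar (3) +
   time (2) + local profile PCs now/3 nightly lags (40) + cloud/precip
   now/lags (8) + synoptic EOF PCs now/3 nights (64). Separate models per
   season and per PC target; leave-one-year-out cross-validation refits
   bases, climatologies and models per fold.
5. **Attribution** — exact double-precision TreeSHAP with group
   aggregation by weather metric and by spatio-temporal scale, and
   reconstruction of favorable/unfavorable wind profiles and synoptic maps
   from SHAP-signed feature averages.
6. **Evaluation** — pooled R² on back-transformed log-density profiles and
   F1 on migration peaks (nights above the per-radar 0.95 density
   quantile), against phenology-only, local-instantaneous-only and
   per-altitude benchmark models.

A synthetic-data generator with planted orthonormal modes, AR(1) synoptic
dynamics and a known linear anomaly response provides ground truth for
every stage.

## Worked example

```r
library(migcast)

cfg <- synthetic_config(n_years = 3, radars = default_radars(4),
                        months_autumn = NULL, seed = 1)
ds  <- generate_dataset(cfg)
panel <- filter_insects(build_nightly_profiles(ds$raw))
panel
#> <profile_panel> 4097 profiles x 13 altitude bins (0-3000 m), 4 radars

pl <- fit_pipeline(panel, ds$local, ds$synoptic, ds$radars)
pl$bird_basis
#> <fpca_basis> bird: 2 components on 13 bins, explained 72.5% + 25.0%

cv <- cross_validate_years(panel, ds$local, ds$synoptic, ds$radars,
                           models = c("full", "local_only", "phenology"),
                           params = gbt_params(nrounds = 80),
                           seasons = "spring")
build_report(cv)
#> Cross-validated forecast performance (overall R^2 / peak F1)
#>
#> -- spring --
#>   full           R2 0.816 +/- 0.008   F1 0.408 +/- 0.261
#>   local_only     R2 0.698 +/- 0.034   F1 0.348 +/- 0.106
#>   phenology      R2 0.602 +/- 0.015   F1 0.029 +/- 0.026
```

Reading the output: the first FPCA component (72.5% of profile variance)
tracks overall migration intensity, the second (25.0%) flight altitude.
The phenology-only forecast already explains 60% of the pooled profile
variance — seasonality is strong — but adding local instantaneous weather
lifts R² to 0.70, and the full design with lagged and synoptic predictors
to 0.82, with the largest gains on peak nights (F1 0.03 → 0.41). That
ordering is the planted truth of the generator: the synthetic anomaly
responds to instantaneous wind support, to mean headwind over the previous
three nights, and to a lagged synoptic score that local instantaneous
predictors cannot see.

For attribution:

```r
ft  <- assemble_features(pl, panel, ds$local, ds$synoptic)
mod <- train_gbt(ft[ft$season == "spring", ], target = "z1")
sh  <- compute_shap(mod, ft[ft$season == "spring", ])
aggregate_shap_groups(sh, metric_groups())   # wind vs temp vs pressure ...
aggregate_shap_groups(sh, scale_groups())    # local vs synoptic, now vs lagged
reconstruct_favorable_patterns(sh, ft[ft$season == "spring", ], pl)
```

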