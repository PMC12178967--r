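Package: migcast
Title: Forecasting Nocturnal Bird Migration from Weather Radar Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forecasts nightly vertical profiles of nocturnal bird migration
    measured by weather radar. Implements functional principal component
    analysis (FPCA) of altitude profiles, empirical orthogonal function (EOF)
    decomposition of synoptic weather fields, day-of-year climatological
    de-trending into standardized anomalies, gradient-boosted tree models of
    the de-trended migration intensity validated by leave-one-year-out
    cross-validation, exact Shapley (SHAP) attribution with feature-group
    aggregation and reconstruction of favorable weather patterns, and forecast
    evaluation by pooled R-squared and migration-peak F1 scores. A synthetic
    data generator with planted, recoverable structure supports end-to-end
    property testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    mclust,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
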