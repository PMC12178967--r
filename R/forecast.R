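# Gradient-boosted tree models of the standardized bird-PC anomalies,
# benchmark models, hyperparameter search and leave-one-year-out
# cross-validation.
#
# Boosting uses xgboost with leaf-wise (lossguide) growth, squared-error
# loss and native handling of missing lag markers; single-threaded so that
# results are bit-reproducible.

#' Default gradient-boosting parameters
#'
#' @param nrounds Number of trees.
#' @param max_leaves Leaves per tree (leaf-wise growth).
#' @param eta Learning rate.
#' @param lambda,alpha L2/L1 regularization.
#' @param min_child_weight Minimum hessian per leaf.
#' @param max_bin Histogram bins per feature for split finding.
#' @return Named list of parameters for [train_gbt()].
#' @export
gbt_params <- function(nrounds = 150, max_leaves = 15, eta = 0.1,
                       lambda = 1, alpha = 0, min_child_weight = 10,
                       max_bin = 64) {
  list(nrounds = nrounds, max_leaves = max_leaves, eta = eta,
       lambda = lambda, alpha = alpha, min_child_weight = min_child_weight,
       max_bin = max_bin)
}

.feature_matrix <- function(ft, cols) {
  x <- as.matrix(ft[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Train a gradient-boosted tree ensemble
#'
#' Fits a squared-error ensemble predicting one target column of the feature
#' table from a set of predictor columns. Missing values (lag markers at
#' season starts) are handled natively by the trees.
#'
#' @param ft Feature table from [assemble_features()].
#' @param target Target column name (default `"z1"`).
#' @param params Parameters from [gbt_params()].
#' @param columns Predictor columns (default: the full 117-column ledger).
#' @return Object of class `gbt_model`.
#' @export
train_gbt <- function(ft, target = "z1", params = gbt_params(),
                      columns = feature_columns(ft)) {
  y <- ft[[target]]
  if (is.null(y)) stop("unknown target column: ", target)
  if (stats::var(y, na.rm = TRUE) < 1e-12) {
    stop("degenerate target: zero variance")
  }
  x <- .feature_matrix(ft, columns)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  max_depth = 0, max_leaves = params$max_leaves,
                  grow_policy = "lossguide", tree_method = "hist",
                  lambda = params$lambda, alpha = params$alpha,
                  min_child_weight = params$min_child_weight,
                  max_bin = params$max_bin %||% 64,
                  nthread = 1, seed = 1),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
  structure(
    list(booster = booster, columns = columns, target = target,
         params = params),
    class = "gbt_model"
  )
}

#' @export
predict.gbt_model <- function(object, ft, ...) {
  x <- .feature_matrix(ft, object$columns)
  stats::predict(object$booster, xgboost::xgb.DMatrix(x, missing = NA,
                                                      nthread = 1))
}

#' Predictor columns of the local-instantaneous benchmark
#'
#' Radar characteristics, time characteristics, the ten local profile-PC
#' anomalies and the cloud/precip anomalies at the forecast time only: 17
#' columns, no lags, no synoptic information.
#'
#' @return Character vector of 17 column names.
#' @export
local_only_columns <- function() {
  g <- feature_groups()
  now <- function(x) x[grepl("_now$", x)]
  c(g$radar, g$time, now(g$local_pcs), now(g$cloud_precip))
}

#' Random-search hyperparameter tuning
#'
#' Samples `budget` parameter draws from the search space (trees 50-500,
#' leaves 7-63, learning rate 0.01-0.3 log-uniform, L1/L2 0-10) and keeps
#' the configuration maximizing a cross-validated R^2 objective. The
#' sequential model-based tuner used at production scale is replaced by
#' seeded uniform random search, which shares the same interface and is
#' deterministic given the seed.
#'
#' @param ft Feature table.
#' @param target Target column.
#' @param budget Number of trials (>= 1).
#' @param seed RNG seed for the sampled configurations.
#' @param objective Function(params) -> score to maximize; the default
#'   evaluates leave-one-year-out R^2 of the target on `ft`.
#' @param columns Predictor columns.
#' @return List with `best_params`, `best_score` and the trial `log`
#'   (data.frame, one row per trial, with a running-best column).
#' @export
tune_gbt <- function(ft, target = "z1", budget = 25, seed = 1,
                     objective = NULL, columns = feature_columns(ft)) {
  stopifnot(budget >= 1)
  objective <- objective %||% function(p) {
    .loyo_r2(ft, target, p, columns)
  }
  draws <- with_seed(seed, {
    data.frame(
      nrounds = sample(50:500, budget, replace = TRUE),
      max_leaves = sample(7:63, budget, replace = TRUE),
      eta = exp(runif(budget, log(0.01), log(0.3))),
      lambda = runif(budget, 0, 10),
      alpha = runif(budget, 0, 10),
      min_child_weight = sample(5:30, budget, replace = TRUE)
    )
  })
  scores <- numeric(budget)
  for (i in seq_len(budget)) {
    scores[i] <- objective(as.list(draws[i, ]))
  }
  log <- cbind(draws, score = scores, best_so_far = cummax(scores))
  best <- which.max(scores)
  list(best_params = as.list(draws[best, ]), best_score = scores[best],
       log = log)
}

# leave-one-year-out R^2 on the (standardized-anomaly) target scale
.loyo_r2 <- function(ft, target, params, columns) {
  years <- sort(unique(ft$year))
  if (length(years) < 2) stop("need at least two years for cross-validation")
  obs <- ft[[target]]
  pred <- rep(NA_real_, nrow(ft))
  for (y in years) {
    tr <- ft$year != y
    model <- train_gbt(ft[tr, , drop = FALSE], target, do.call(gbt_params, params),
                       columns)
    pred[!tr] <- predict(model, ft[!tr, , drop = FALSE])
  }
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Predicted log-density profiles from anomaly models
#'
#' Turns predicted standardized anomalies (z1, z2) into 13-bin log-density
#' profiles: destandardize with the radar- and season-specific climatology of
#' each bird PC, then reconstruct through the bird FPCA basis.
#'
#' @param pipeline Fitted [fit_pipeline()].
#' @param ft Feature-table rows to predict for (meta columns are used).
#' @param z Matrix (rows x 2) of predicted standardized anomalies; use zeros
#'   for the phenology benchmark.
#' @return Matrix of predicted log-density profiles (rows x 13).
#' @export
predict_profiles <- function(pipeline, ft, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = pipeline$n_fpca)
  stopifnot(nrow(z) == nrow(ft))
  scores <- matrix(NA_real_, nrow(ft), pipeline$n_fpca)
  for (r in unique(ft$radar)) {
    for (s in c("spring", "autumn")) {
      i <- which(ft$radar == r & ft$season == s)
      if (length(i) == 0) next
      cl <- pipeline$bird_clims[[r]][[s]]
      if (is.null(cl)) stop("no climatology for radar ", r, " season ", s)
      for (k in seq_len(pipeline$n_fpca)) {
        scores[i, k] <- destandardize_anomaly(z[i, k], ft$night[i], cl[[k]])
      }
    }
  }
  fpca_reconstruct(pipeline$bird_basis, scores)
}

#' Phenology benchmark profiles
#'
#' The naive seasonal forecast: standardized anomalies forced to zero, i.e.
#' the climatological day-of-year mean of each bird PC mapped through the
#' FPCA basis. Uses no weather information.
#'
#' @param pipeline Fitted [fit_pipeline()].
#' @param ft Feature-table rows.
#' @return Matrix of predicted log-density profiles.
#' @export
benchmark_phenology <- function(pipeline, ft) {
  predict_profiles(pipeline, ft, matrix(0, nrow(ft), pipeline$n_fpca))
}

# per-altitude benchmark design: one row per (profile row x altitude bin),
# raw local weather at that bin only, plus height and radar/time columns
.per_altitude_table <- function(ft, profiles, local, altitudes) {
  key_ft <- paste(ft$radar, ft$night, ft$slot)
  key_loc <- paste(local$meta$radar, local$meta$night, local$meta$slot)
  li <- match(key_ft, key_loc)
  key_prof <- paste(profiles$meta$radar, profiles$meta$night,
                    profiles$meta$slot)
  pi <- match(key_ft, key_prof)
  nbin <- length(altitudes)
  n <- nrow(ft)
  rows <- rep(seq_len(n), each = nbin)
  bins <- rep(seq_len(nbin), times = n)
  out <- data.frame(
    row = rows, bin = bins,
    height = altitudes[bins],
    lon = ft$lon[rows], lat = ft$lat[rows], antenna = ft$antenna[rows],
    solar_decl = ft$solar_decl[rows], time_angle = ft$time_angle[rows]
  )
  for (v in LOCAL_VARS) {
    out[[v]] <- local$profiles[[v]][cbind(li[rows], bins)]
  }
  out$cloud <- local$cloud[li[rows]]
  out$precip <- local$precip[li[rows]]
  obs <- profiles$values
  obs[!profiles$valid] <- NA
  out$logdens <- obs[cbind(pi[rows], bins)]
  out
}

#' Per-altitude benchmark model
#'
#' A single ensemble over rows of (radar, night, slot, height) predicting
#' the log density of each altitude bin from the raw (non-PC) local weather
#' at that height, the height itself, and the radar/time characteristics.
#' No lagged and no synoptic predictors.
#'
#' @param ft_train,ft_test Feature-table rows (meta columns used for
#'   alignment).
#' @param profiles Observed bird [profile_panel()].
#' @param local Local weather panel.
#' @param params [gbt_params()].
#' @return List with the fitted `model` and `pred`, the predicted
#'   log-density profile matrix for `ft_test` rows.
#' @export
benchmark_per_altitude <- function(ft_train, ft_test, profiles, local,
                                   params = gbt_params()) {
  alts <- profiles$altitudes
  cols <- c("height", "lon", "lat", "antenna", "solar_decl", "time_angle",
            LOCAL_VARS, "cloud", "precip")
  tab_tr <- .per_altitude_table(ft_train, profiles, local, alts)
  tab_tr <- tab_tr[!is.na(tab_tr$logdens), , drop = FALSE]
  model <- train_gbt(tab_tr, target = "logdens", params = params,
                     columns = cols)
  list(model = model,
       pred = predict_per_altitude(model, ft_test, profiles, local))
}

#' @rdname benchmark_per_altitude
#' @param model Fitted per-altitude `gbt_model`.
#' @param ft Feature-table rows to predict for.
#' @export
predict_per_altitude <- function(model, ft, profiles, local) {
  alts <- profiles$altitudes
  tab <- .per_altitude_table(ft, profiles, local, alts)
  p <- predict(model, tab)
  matrix(p[order(tab$row, tab$bin)], nrow(ft), length(alts), byrow = TRUE)
}
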