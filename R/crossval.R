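# Leave-one-year-out cross-validation of the full forecasting pipeline and
# its benchmarks. For every held-out year the bases, climatologies and
# models are refit from scratch on the remaining years (no leakage), the
# held-out year is predicted, and forecasts are scored on back-transformed
# log-density profiles (pooled R^2) and on migration peaks (F1).

#' Leave-one-year-out cross-validation
#'
#' For each held-out year and each season, refits the fold pipeline
#' ([fit_pipeline()]) and the requested models on the remaining years,
#' predicts the held-out rows, and evaluates. Models:
#' \describe{
#'   \item{full}{117-predictor gradient-boosted model of both bird-PC
#'     standardized anomalies.}
#'   \item{local_only}{same pipeline restricted to the 17 local,
#'     instantaneous columns ([local_only_columns()]).}
#'   \item{per_altitude}{per-bin model from raw local weather at each
#'     height ([benchmark_per_altitude()]).}
#'   \item{phenology}{climatological day-of-year forecast, no weather.}
#' }
#' Peak truth labels use the observed per-radar-season density-index
#' distribution; predicted labels use thresholds derived from the model's
#' training-year predictions.
#'
#' @param profiles Preprocessed bird [profile_panel()].
#' @param local,synoptic Weather panels.
#' @param radars Radar table.
#' @param models Character subset of
#'   `c("full", "local_only", "per_altitude", "phenology")`.
#' @param params [gbt_params()] shared by all tree models.
#' @param seasons Seasons to evaluate.
#' @param months_spring,months_autumn Season windows.
#' @param peak_q Peak quantile (default 0.95).
#' @param peak_threshold_source Where predicted-label thresholds come from:
#'   `"training"` (default; the quantile of the model's training-year
#'   predictions, as available operationally) or `"heldout"` (the quantile
#'   of the held-out year's own predictions).
#' @param keep_fold_models Keep boosters and held-out features per fold
#'   (needed for SHAP pooling; default TRUE).
#' @param verbose Print fold progress.
#' @return Object of class `mig_cv`: `results` (per model, season, year:
#'   `r2`, `f1`), and `folds` (per year: pipeline summary, models, held-out
#'   feature tables and predictions).
#' @export
cross_validate_years <- function(profiles, local, synoptic, radars,
                                 models = c("full", "local_only", "phenology"),
                                 params = gbt_params(),
                                 seasons = c("spring", "autumn"),
                                 months_spring = 2:5, months_autumn = 7:11,
                                 peak_q = 0.95,
                                 peak_threshold_source = c("training", "heldout"),
                                 keep_fold_models = TRUE,
                                 verbose = FALSE) {
  peak_threshold_source <- match.arg(peak_threshold_source)
  stop_if_not_panel(profiles)
  models <- match.arg(models, c("full", "local_only", "per_altitude",
                                "phenology"), several.ok = TRUE)
  years <- sort(unique(night_year(profiles$meta$night)))
  if (length(years) < 2) stop("need at least two years")

  obs_vals <- profiles$values
  obs_vals[!profiles$valid] <- NA

  # observed peak truth: per radar-season thresholds over all years
  season_p <- night_season(profiles$meta$night, months_spring, months_autumn)
  obs_idx <- nightly_density_index(profiles$meta, obs_vals)
  obs_idx$season <- night_season(obs_idx$night, months_spring, months_autumn)
  obs_idx$year <- night_year(obs_idx$night)
  obs_idx$peak <- NA
  for (r in unique(obs_idx$radar)) {
    for (s in seasons) {
      i <- which(obs_idx$radar == r & obs_idx$season == s)
      if (length(i) == 0) next
      obs_idx$peak[i] <- identify_peaks(obs_idx$index[i], q = peak_q)
    }
  }

  results <- list()
  folds <- list()
  for (y in years) {
    if (verbose) message("fold: held-out year ", y)
    train_years <- setdiff(years, y)
    pipeline <- fit_pipeline(profiles, local, synoptic, radars,
                             train_years = train_years,
                             months_spring = months_spring,
                             months_autumn = months_autumn)
    ft <- assemble_features(pipeline, profiles, local, synoptic)
    fold <- list(year = y, pipeline = pipeline, models = list(),
                 features = if (keep_fold_models) ft[ft$year == y, ] else NULL)

    for (s in seasons) {
      tr <- ft$year != y & ft$season == s
      te <- ft$year == y & ft$season == s
      if (sum(te) == 0) {
        warning("no rows for season ", s, " in year ", y, "; skipped")
        next
      }
      ft_tr <- ft[tr, , drop = FALSE]
      ft_te <- ft[te, , drop = FALSE]
      # observed profiles aligned to feature rows
      key_prof <- paste(profiles$meta$radar, profiles$meta$night,
                        profiles$meta$slot)
      pi_te <- match(paste(ft_te$radar, ft_te$night, ft_te$slot), key_prof)
      pi_tr <- match(paste(ft_tr$radar, ft_tr$night, ft_tr$slot), key_prof)
      obs_te <- obs_vals[pi_te, , drop = FALSE]

      for (m in models) {
        pr <- switch(m,
          full = , local_only = {
            cols <- if (m == "full") feature_columns(ft) else local_only_columns()
            z_te <- matrix(NA_real_, sum(te), 2)
            z_tr <- matrix(NA_real_, sum(tr), 2)
            mods <- list()
            for (k in 1:2) {
              mod <- train_gbt(ft_tr, target = paste0("z", k),
                               params = params, columns = cols)
              z_te[, k] <- predict(mod, ft_te)
              z_tr[, k] <- predict(mod, ft_tr)
              mods[[k]] <- mod
            }
            if (keep_fold_models) fold$models[[m]][[s]] <- mods
            list(te = predict_profiles(pipeline, ft_te, z_te),
                 tr = predict_profiles(pipeline, ft_tr, z_tr))
          },
          phenology = {
            list(te = benchmark_phenology(pipeline, ft_te),
                 tr = benchmark_phenology(pipeline, ft_tr))
          },
          per_altitude = {
            ba <- benchmark_per_altitude(ft_tr, ft_te, profiles, local,
                                         params = params)
            list(te = ba$pred,
                 tr = predict_per_altitude(ba$model, ft_tr, profiles, local))
          }
        )

        r2 <- r2_profiles(pr$te, obs_te)

        # peak F1: predicted thresholds from training-year predictions
        idx_te <- nightly_density_index(ft_te, pr$te)
        idx_tr <- nightly_density_index(ft_tr, pr$tr)
        pred_peak <- rep(NA, nrow(idx_te))
        for (r in unique(idx_te$radar)) {
          i <- which(idx_te$radar == r)
          thr <- if (peak_threshold_source == "training") {
            stats::quantile(idx_tr$index[idx_tr$radar == r], peak_q,
                            na.rm = TRUE, names = FALSE)
          } else {
            NULL
          }
          pred_peak[i] <- identify_peaks(idx_te$index[i], q = peak_q,
                                         threshold = thr)
        }
        truth_peak <- obs_idx$peak[match(
          paste(idx_te$radar, idx_te$night),
          paste(obs_idx$radar, obs_idx$night))]
        f1 <- f1_peaks(truth_peak, pred_peak)

        results[[length(results) + 1]] <- data.frame(
          model = m, season = s, year = y, r2 = r2, f1 = as.numeric(f1)
        )
        if (keep_fold_models) {
          fold$pred[[m]][[s]] <- pr$te
        }
      }
    }
    folds[[as.character(y)]] <- fold
  }
  structure(
    list(results = do.call(rbind, results), folds = folds,
         models = models, seasons = seasons, years = years,
         params = params, peak_q = peak_q),
    class = "mig_cv"
  )
}

#' @export
print.mig_cv <- function(x, ...) {
  cat(sprintf("<mig_cv> %d folds x models [%s] x seasons [%s]\n",
              length(x$folds), paste(x$models, collapse = ", "),
              paste(x$seasons, collapse = ", ")))
  print(build_report(x))
  invisible(x)
}

#' Mean cross-validated R^2 per model
#'
#' Convenience accessor: average of the per-year R^2 across folds, per model
#' and season (or pooled over seasons).
#'
#' @param cv A `mig_cv`.
#' @param by_season Keep seasons separate (default FALSE).
#' @return Named numeric vector (or data.frame when `by_season`).
#' @export
cv_mean_r2 <- function(cv, by_season = FALSE) {
  d <- cv$results
  if (by_season) {
    out <- stats::aggregate(r2 ~ model + season, data = d, FUN = mean)
    return(out)
  }
  v <- tapply(d$r2, d$model, mean)
  v[cv$models]
}
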