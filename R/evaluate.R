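# Forecast evaluation: pooled R^2 on back-transformed log-density profiles
# and migration-peak identification (per-radar 0.95-quantile threshold, F1).

#' Pooled R-squared over profile cells
#'
#' `1 - SSE/SST` pooled over every valid (profile row, altitude bin) cell,
#' with SST around the pooled mean of the observations. This scores the
#' back-transformed forecasts on the log-density scale on which the models
#' are compared.
#'
#' @param predicted,observed Numeric matrices of identical shape.
#' @param valid Optional logical matrix; `FALSE` cells are ignored (defaults
#'   to non-NA observed cells).
#' @return R^2 (can be negative for forecasts worse than the pooled mean).
#' @export
r2_profiles <- function(predicted, observed, valid = NULL) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  stopifnot(identical(dim(predicted), dim(observed)))
  valid <- valid %||% !is.na(observed)
  valid <- valid & !is.na(observed) & !is.na(predicted)
  if (sum(valid) < 2) stop("need at least two valid cells")
  obs <- observed[valid]
  err <- predicted[valid] - obs
  1 - sum(err^2) / sum((obs - mean(obs))^2)
}

#' Identify migration-peak nights
#'
#' A night is a peak when its density index strictly exceeds the empirical
#' `q` quantile of the reference values (by default the values themselves).
#' The strict inequality means ties never inflate peak prevalence; on `n`
#' distinct values exactly `floor(n * (1 - q))` nights are flagged.
#'
#' @param x Numeric vector of nightly density indices for one radar-season.
#' @param q Quantile defining peaks (default 0.95, the top 5%).
#' @param threshold Optional externally derived threshold (e.g. from
#'   training years); overrides the quantile of `x`.
#' @return Logical vector of peak labels.
#' @export
identify_peaks <- function(x, q = 0.95, threshold = NULL) {
  if (is.null(threshold)) {
    if (length(stats::na.omit(x)) == 0) return(rep(NA, length(x)))
    threshold <- stats::quantile(x, q, na.rm = TRUE, names = FALSE)
  }
  if (isTRUE(max(x, na.rm = TRUE) == min(x, na.rm = TRUE))) {
    warning("all values identical; no peaks identified")
  }
  x > threshold
}

#' F1 score for peak identification
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`. When there are neither true nor predicted
#' peaks (TP + FP + FN = 0) the score is reported as 0 with attribute
#' `undefined = TRUE`.
#'
#' @param truth,predicted Logical label vectors of equal length.
#' @return F1 in `[0, 1]`.
#' @export
f1_peaks <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label length mismatch")
  ok <- !is.na(truth) & !is.na(predicted)
  truth <- truth[ok]
  predicted <- predicted[ok]
  tp <- sum(truth & predicted)
  fp <- sum(!truth & predicted)
  fn <- sum(truth & !predicted)
  if (tp + fp + fn == 0) {
    return(structure(0, undefined = TRUE))
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Nightly density index per radar
#'
#' The scalar nightly migration intensity used for peak detection: the mean
#' log density over all slots and valid altitude bins of a radar-night.
#'
#' @param meta data.frame with `radar`, `night` (one row per profile).
#' @param values Log-density matrix aligned with `meta`.
#' @param valid Optional validity mask.
#' @return data.frame with `radar`, `night`, `index`.
#' @export
nightly_density_index <- function(meta, values, valid = NULL) {
  values <- as.matrix(values)
  valid <- valid %||% !is.na(values)
  v <- values
  v[!valid] <- NA
  dt <- data.table::data.table(radar = meta$radar, night = meta$night,
                               m = rowMeans(v, na.rm = TRUE))
  out <- dt[, .(index = mean(m, na.rm = TRUE)), by = .(radar, night)]
  as.data.frame(out)
}

#' Build the evaluation report
#'
#' Summarizes cross-validation results into the per-year and total (mean
#' +/- sd across years) table of overall R^2 and peak F1 per model and
#' season.
#'
#' @param cv A `mig_cv` object from [cross_validate_years()].
#' @return Object of class `mig_report`: list with `per_year` (model,
#'   season, year, r2, f1) and `totals` (model, season, means and sds).
#' @export
build_report <- function(cv) {
  per_year <- cv$results
  sp <- split(per_year, list(per_year$model, per_year$season), drop = TRUE)
  totals <- do.call(rbind, lapply(sp, function(d) {
    data.frame(model = d$model[1], season = d$season[1],
               n_years = nrow(d),
               r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
               f1_mean = mean(d$f1), f1_sd = stats::sd(d$f1))
  }))
  rownames(totals) <- NULL
  structure(list(per_year = per_year, totals = totals), class = "mig_report")
}

#' @export
print.mig_report <- function(x, digits = 3, ...) {
  cat("Cross-validated forecast performance (overall R^2 / peak F1)\n\n")
  t <- x$totals
  for (s in unique(t$season)) {
    cat(sprintf("-- %s --\n", s))
    d <- t[t$season == s, ]
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %-14s R2 %5.3f +/- %.3f   F1 %5.3f +/- %.3f\n",
                  d$model[i], d$r2_mean[i], d$r2_sd[i],
                  d$f1_mean[i], d$f1_sd[i]))
    }
  }
  invisible(x)
}
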