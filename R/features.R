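# Fold pipeline (bases + climatologies fitted on training years only) and
# assembly of the 117-predictor feature table:
#   3  radar characteristics (lon, lat, antenna height)
#   2  time characteristics (solar declination, time-of-day angle)
#   40 local-profile PC anomalies (5 vars x 2 PCs x [now + 3 previous nights])
#   8  cloudiness & precipitation anomalies (2 x [now + 3 previous nights])
#   64 synoptic EOF PCs (4 vars x 4 PCs x [now + 3 previous nights])
# The "previous nights" slices are nightly averages for the local block and
# the nightly value for the synoptic block; the synoptic EOFs are computed on
# fields already expressed as anomalies from a day-of-year climatology.

FEATURE_SLICES <- c("now", "lag1", "lag2", "lag3")

# the fixed, deterministic predictor-column ledger
feature_column_ledger <- function() {
  local_cols <- as.vector(t(outer(
    as.vector(t(outer(LOCAL_VARS, 1:2, function(v, p) paste0(v, "_pc", p)))),
    FEATURE_SLICES, paste, sep = "_"
  )))
  scalar_cols <- as.vector(t(outer(c("cloud", "precip"), FEATURE_SLICES,
                                   paste, sep = "_")))
  syn_cols <- as.vector(t(outer(
    as.vector(t(outer(SYNOPTIC_VARS, 1:4, function(v, p) paste0(v, "_eof", p)))),
    FEATURE_SLICES, paste, sep = "_"
  )))
  list(
    radar = c("lon", "lat", "antenna"),
    time = c("solar_decl", "time_angle"),
    local_pcs = local_cols,
    cloud_precip = scalar_cols,
    synoptic_pcs = syn_cols
  )
}

#' Names of the predictor columns of a feature table
#'
#' @param ft A feature table from [assemble_features()] (or nothing, for the
#'   canonical ledger).
#' @return Character vector of the 117 predictor names, in fixed order.
#' @export
feature_columns <- function(ft = NULL) {
  if (!is.null(ft)) {
    fc <- attr(ft, "feature_columns")
    if (!is.null(fc)) return(fc)
  }
  unlist(feature_column_ledger(), use.names = FALSE)
}

#' Feature groups of the 117-predictor design
#'
#' `feature_groups()` returns the five structural groups (radar, time, local
#' profile PCs, cloud/precip, synoptic PCs). `metric_groups()` groups the
#' weather predictors by physical metric (Eastward wind, Northward wind,
#' Temperature, Pressure, Humidity, Cloudiness, Precipitation).
#' `scale_groups()` groups them by spatio-temporal scale (Local, Synoptic,
#' and their previous-3-nights counterparts). Radar and time characteristics
#' belong to no weather group.
#'
#' @return Named list of character vectors of column names.
#' @export
feature_groups <- function() feature_column_ledger()

#' @rdname feature_groups
#' @export
metric_groups <- function() {
  cols <- feature_column_ledger()
  all_weather <- c(cols$local_pcs, cols$cloud_precip, cols$synoptic_pcs)
  pick <- function(prefixes) {
    all_weather[sub("_.*$", "", all_weather) %in% prefixes]
  }
  list(
    `Eastward wind` = pick("u"),
    `Northward wind` = pick("v"),
    Temperature = pick(c("temp", "t850")),
    Pressure = pick(c("pres", "msl")),
    Humidity = pick(c("rh", "rh850")),
    Cloudiness = pick(c("cloud", "clc")),
    Precipitation = pick("precip")
  )
}

#' @rdname feature_groups
#' @export
scale_groups <- function() {
  cols <- feature_column_ledger()
  local_all <- c(cols$local_pcs, cols$cloud_precip)
  syn_all <- cols$synoptic_pcs
  is_now <- function(x) grepl("_now$", x)
  list(
    Local = local_all[is_now(local_all)],
    Synoptic = syn_all[is_now(syn_all)],
    `Local previous 3 nights` = local_all[!is_now(local_all)],
    `Synoptic previous 3 nights` = syn_all[!is_now(syn_all)]
  )
}

#' Fit the per-fold modelling pipeline
#'
#' Fits every data-driven component on the training years only: the bird
#' FPCA basis and the radar- and season-specific climatologies of its
#' scores, the local-variable FPCA bases and per-radar score climatologies,
#' the per-radar cloud/precip climatologies, and per synoptic variable the
#' day-of-year cell climatology plus the EOF basis of the resulting anomaly
#' fields (with scores stored for every night).
#'
#' @param profiles Bird log-density [profile_panel()] (preprocessed).
#' @param local Local weather panel (see [generate_weather()]).
#' @param synoptic Synoptic field panel.
#' @param radars Radar table (`id`, `lon`, `lat`, `antenna`).
#' @param train_years Integer years used for fitting; others are held out.
#' @param months_spring,months_autumn Season windows (month numbers).
#' @param n_fpca,n_eof Component counts (defaults 2 and 4).
#' @param bandwidth Climatology bandwidth in days.
#' @return Object of class `mig_pipeline`.
#' @export
fit_pipeline <- function(profiles, local, synoptic, radars,
                         train_years = NULL,
                         months_spring = 2:5, months_autumn = 7:11,
                         n_fpca = 2, n_eof = 4, bandwidth = 15) {
  stop_if_not_panel(profiles)
  years_b <- night_year(profiles$meta$night)
  train_years <- train_years %||% sort(unique(years_b))
  tr_b <- years_b %in% train_years

  # bird basis on fully valid training profiles; score climatologies per
  # radar and season on all training rows (missing bins mean-imputed)
  vals <- profiles$values
  vals[!profiles$valid] <- NA
  bird_basis <- fit_fpca(vals[tr_b, , drop = FALSE], n_components = n_fpca,
                         altitudes = profiles$altitudes, variable = "bird")
  sc <- fpca_scores(bird_basis, vals[tr_b, , drop = FALSE])
  meta_tr <- profiles$meta[tr_b, , drop = FALSE]
  season_tr <- night_season(meta_tr$night, months_spring, months_autumn)
  bird_clims <- list()
  for (r in radars$id) {
    for (s in c("spring", "autumn")) {
      i <- which(meta_tr$radar == r & season_tr == s)
      if (length(i) == 0) next
      for (k in seq_len(n_fpca)) {
        bird_clims[[r]][[s]][[k]] <- fit_climatology(
          sc[i, k], meta_tr$night[i], bandwidth = bandwidth,
          name = sprintf("bird pc%d %s %s", k, r, s)
        )
      }
    }
  }

  # local bases and per-radar climatologies
  years_l <- night_year(local$meta$night)
  tr_l <- years_l %in% train_years
  local_bases <- list()
  local_clims <- list()
  for (v in LOCAL_VARS) {
    local_bases[[v]] <- fit_fpca(local$profiles[[v]][tr_l, , drop = FALSE],
                                 n_components = n_fpca,
                                 altitudes = local$altitudes, variable = v)
    sc_v <- fpca_scores(local_bases[[v]], local$profiles[[v]])
    for (r in radars$id) {
      i <- which(tr_l & local$meta$radar == r)
      for (k in seq_len(n_fpca)) {
        local_clims[[r]][[v]][[k]] <- fit_climatology(
          sc_v[i, k], local$meta$night[i], bandwidth = bandwidth,
          name = sprintf("%s pc%d %s", v, k, r)
        )
      }
    }
  }
  cloud_clims <- list()
  precip_clims <- list()
  for (r in radars$id) {
    i <- which(tr_l & local$meta$radar == r)
    cloud_clims[[r]] <- fit_climatology(local$cloud[i], local$meta$night[i],
                                        bandwidth = bandwidth,
                                        name = paste("cloud", r))
    precip_clims[[r]] <- fit_climatology(local$precip[i], local$meta$night[i],
                                         bandwidth = bandwidth,
                                         name = paste("precip", r))
  }

  # synoptic: per-cell climatology -> anomalies -> EOF (train nights only),
  # scores stored for every night
  years_s <- night_year(synoptic$nights)
  tr_s <- years_s %in% train_years
  eof_bases <- list()
  syn_scores <- data.frame(night = synoptic$nights)
  doys_out <- sort(unique(doy_index(synoptic$nights)))
  for (v in SYNOPTIC_VARS) {
    mu <- field_climatology(synoptic$fields[[v]][tr_s, , drop = FALSE],
                            synoptic$nights[tr_s], bandwidth = bandwidth,
                            doys_out = doys_out)
    anom <- field_anomalies(synoptic$fields[[v]], synoptic$nights, mu)
    eof_bases[[v]] <- fit_eof(anom[tr_s, , drop = FALSE], synoptic$grid,
                              n_components = n_eof, variable = v)
    s <- eof_scores(eof_bases[[v]], anom)
    colnames(s) <- paste0(v, "_eof", seq_len(n_eof))
    syn_scores <- cbind(syn_scores, as.data.frame(s))
  }

  structure(
    list(bird_basis = bird_basis, bird_clims = bird_clims,
         local_bases = local_bases, local_clims = local_clims,
         cloud_clims = cloud_clims, precip_clims = precip_clims,
         eof_bases = eof_bases, synoptic_scores = syn_scores,
         radars = radars, train_years = train_years,
         months_spring = months_spring, months_autumn = months_autumn,
         n_fpca = n_fpca, n_eof = n_eof, bandwidth = bandwidth),
    class = "mig_pipeline"
  )
}

#' @export
print.mig_pipeline <- function(x, ...) {
  cat(sprintf("<mig_pipeline> trained on years %s; %d radars\n",
              paste(x$train_years, collapse = ", "), nrow(x$radars)))
  invisible(x)
}

#' Assemble the 117-predictor feature table
#'
#' One row per (radar, night, slot) bird profile. Targets `z1`, `z2` are the
#' standardized anomalies of the two bird FPCA scores (radar- and
#' season-specific climatologies); predictors are the five feature groups
#' described in [feature_groups()]. Lag slices that reach before the start
#' of the data carry explicit `NA` missing markers. Rows outside the two
#' season windows are dropped.
#'
#' @param pipeline A fitted [fit_pipeline()] object.
#' @param profiles,local,synoptic Data panels (any years; the pipeline's
#'   training years only matter for what was fitted).
#' @return data.frame with meta columns (`radar`, `night`, `slot`, `season`,
#'   `year`), target columns (`z1`, `z2`) and the 117 predictors, with
#'   attribute `feature_columns`.
#' @export
assemble_features <- function(pipeline, profiles, local, synoptic) {
  stopifnot(inherits(pipeline, "mig_pipeline"))
  stop_if_not_panel(profiles)
  radars <- pipeline$radars
  n_fpca <- pipeline$n_fpca

  # targets
  vals <- profiles$values
  vals[!profiles$valid] <- NA
  sc <- fpca_scores(pipeline$bird_basis, vals)
  meta <- profiles$meta
  season <- night_season(meta$night, pipeline$months_spring,
                         pipeline$months_autumn)
  z <- matrix(NA_real_, nrow(meta), n_fpca)
  for (r in radars$id) {
    for (s in c("spring", "autumn")) {
      i <- which(meta$radar == r & season == s)
      if (length(i) == 0) next
      cl <- pipeline$bird_clims[[r]][[s]]
      if (is.null(cl)) next
      for (k in seq_len(n_fpca)) {
        z[i, k] <- standardize_anomaly(sc[i, k], meta$night[i], cl[[k]])
      }
    }
  }

  keep <- !is.na(season) & !is.na(z[, 1])
  ft <- data.frame(radar = meta$radar[keep], night = meta$night[keep],
                   slot = meta$slot[keep], season = season[keep],
                   year = night_year(meta$night[keep]))
  ft$z1 <- z[keep, 1]
  ft$z2 <- if (n_fpca >= 2) z[keep, 2] else NA_real_

  # radar and time characteristics
  ri <- match(ft$radar, radars$id)
  ft$lon <- radars$lon[ri]
  ft$lat <- radars$lat[ri]
  ft$antenna <- radars$antenna[ri]
  ft$solar_decl <- solar_declination(ft$night)
  slot_hour <- SLOT_HOURS[ft$slot]
  ft$time_angle <- 2 * pi * slot_hour / 24

  # local anomaly block: slot-level "now" + nightly-mean lags
  lmeta <- local$meta
  anom_now <- data.table::data.table(radar = lmeta$radar, night = lmeta$night,
                                     slot = lmeta$slot)
  for (v in LOCAL_VARS) {
    sc_v <- fpca_scores(pipeline$local_bases[[v]], local$profiles[[v]])
    for (k in seq_len(n_fpca)) {
      a <- rep(NA_real_, nrow(lmeta))
      for (r in radars$id) {
        i <- which(lmeta$radar == r)
        a[i] <- anomaly(sc_v[i, k], lmeta$night[i],
                        pipeline$local_clims[[r]][[v]][[k]])
      }
      anom_now[[paste0(v, "_pc", k)]] <- a
    }
  }
  for (nm in c("cloud", "precip")) {
    x <- local[[nm]]
    clims <- pipeline[[paste0(nm, "_clims")]]
    a <- rep(NA_real_, nrow(lmeta))
    for (r in radars$id) {
      i <- which(lmeta$radar == r)
      a[i] <- anomaly(x[i], lmeta$night[i], clims[[r]])
    }
    anom_now[[nm]] <- a
  }

  anom_cols <- setdiff(names(anom_now), c("radar", "night", "slot"))
  nightly <- anom_now[, lapply(.SD, mean), by = .(radar, night),
                      .SDcols = anom_cols]

  ftd <- data.table::as.data.table(ft)
  ftd <- merge(ftd, anom_now, by = c("radar", "night", "slot"),
               all.x = TRUE, sort = FALSE)
  data.table::setnames(ftd, anom_cols, paste0(anom_cols, "_now"))
  for (j in 1:3) {
    lagged <- data.table::copy(nightly)
    lagged[, night := night + j]
    data.table::setnames(lagged, anom_cols, paste0(anom_cols, "_lag", j))
    ftd <- merge(ftd, lagged, by = c("radar", "night"),
                 all.x = TRUE, sort = FALSE)
  }

  # synoptic block: nightly EOF scores, now + previous 3 nights
  ss <- data.table::as.data.table(pipeline$synoptic_scores)
  syn_cols <- setdiff(names(ss), "night")
  ssn <- data.table::copy(ss)
  data.table::setnames(ssn, syn_cols, paste0(syn_cols, "_now"))
  ftd <- merge(ftd, ssn, by = "night", all.x = TRUE, sort = FALSE)
  for (j in 1:3) {
    lagged <- data.table::copy(ss)
    lagged[, night := night + j]
    data.table::setnames(lagged, syn_cols, paste0(syn_cols, "_lag", j))
    ftd <- merge(ftd, lagged, by = "night", all.x = TRUE, sort = FALSE)
  }

  out <- as.data.frame(ftd)
  cols <- feature_columns()
  missing_cols <- setdiff(cols, names(out))
  if (length(missing_cols) > 0) {
    stop("internal error: feature columns not assembled: ",
         paste(missing_cols, collapse = ", "))
  }
  meta_cols <- c("radar", "night", "slot", "season", "year", "z1", "z2")
  out <- out[order(out$radar, out$night, match(out$slot, c("early", "mid", "late"))),
             c(meta_cols, cols)]
  rownames(out) <- NULL
  stopifnot(length(cols) == 117)
  attr(out, "feature_columns") <- cols
  out
}
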