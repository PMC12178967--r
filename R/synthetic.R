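# Synthetic radar-night generator with planted, recoverable structure.
#
# Every downstream stage is tested against this generator's ground truth:
# orthonormal vertical modes and synoptic spatial modes (recoverable by
# FPCA/EOF), smooth day-of-year phenology (recoverable by the climatology),
# and a linear anomaly response to wind support, lagged headwind and lagged
# synoptic scores (recoverable by the gradient-boosted models and SHAP).

#' Default synthetic radar network
#'
#' Nine radar sites spread over a France-like domain, with identifiers,
#' coordinates and antenna heights. Purely synthetic placements.
#'
#' @param n Number of radars (default 9).
#' @return data.frame with columns `id`, `lon`, `lat`, `antenna`.
#' @export
default_radars <- function(n = 9) {
  full <- data.frame(
    id = sprintf("R%02d", 1:9),
    lon = c(2.0, -0.6, 2.4, -0.1, 6.2, 4.4, 5.1, 1.4, -1.6),
    lat = c(50.1, 44.8, 47.1, 48.9, 48.7, 43.8, 45.7, 43.6, 47.3),
    antenna = c(85, 60, 180, 120, 310, 75, 590, 200, 45)
  )
  stopifnot(n >= 1, n <= 9)
  full[seq_len(n), , drop = FALSE]
}

#' Configuration for the synthetic generator
#'
#' The defaults define the study conditions emulated throughout the package:
#' 6 years of nightly observations at 9 radars during the spring (Feb-May)
#' and autumn (Jul-Nov) migration windows, 13 altitude bins (0-3000 m by
#' 250 m), synoptic fields on the fixed 0.5-degree grid (-20..10 E,
#' 10..70 N), planted anomaly effect sizes (beta, gamma, delta) =
#' (0.8, 0.5, 0.5) in standardized predictor units, anomaly noise sd 0.5,
#' 5% insect-contaminated events and 5% missing altitude bins.
#'
#' @param n_years Number of consecutive years (default 6).
#' @param start_year First year (default 2017).
#' @param radars Radar table as from [default_radars()].
#' @param months_spring,months_autumn Month numbers of the two season
#'   windows.
#' @param effect_sizes Named list: `beta_wind_now` (instantaneous wind
#'   support), `gamma_headwind_lag` (mean headwind over the previous 3
#'   nights), `delta_synoptic_lag` (mean synoptic score over the previous 3
#'   nights), each per standardized unit.
#' @param noise_sd Residual sd of the planted standardized anomaly.
#' @param insect_rate Fraction of insect-contaminated events in `[0, 1]`.
#' @param missing_rate Fraction of altitude bins dropped at random.
#' @param ar_coef AR(1) coefficient of the daily synoptic score series.
#' @param profile_noise_sd Per-bin measurement noise sd of a single raw
#'   sub-profile (log10 units).
#' @param synoptic_noise_scale,local_noise_scale Multipliers on the weather
#'   noise terms (1 = nominal; 0 gives noise-free weather for exact recovery
#'   tests).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 6, start_year = 2017,
                             radars = default_radars(),
                             months_spring = 2:5, months_autumn = 7:11,
                             effect_sizes = list(beta_wind_now = 0.8,
                                                 gamma_headwind_lag = 0.5,
                                                 delta_synoptic_lag = 0.5),
                             noise_sd = 0.5, insect_rate = 0.05,
                             missing_rate = 0.05, ar_coef = 0.8,
                             profile_noise_sd = 0.1,
                             synoptic_noise_scale = 1, local_noise_scale = 1,
                             seed = 1) {
  if (n_years < 1) stop("n_years must be positive")
  if (is.null(radars) || nrow(radars) == 0) stop("radar list must not be empty")
  stopifnot(insect_rate >= 0, insect_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            abs(ar_coef) < 1, noise_sd >= 0)
  need <- c("beta_wind_now", "gamma_headwind_lag", "delta_synoptic_lag")
  if (!all(need %in% names(effect_sizes))) {
    stop("effect_sizes must name ", paste(need, collapse = ", "))
  }
  grid <- make_grid()
  stopifnot(grid$n_cells == 121 * 61)
  structure(
    list(n_years = n_years, start_year = start_year, radars = radars,
         months_spring = months_spring, months_autumn = months_autumn,
         grid = grid, altitudes = mig_altitudes(),
         effect_sizes = effect_sizes, noise_sd = noise_sd,
         insect_rate = insect_rate, missing_rate = missing_rate,
         ar_coef = ar_coef, profile_noise_sd = profile_noise_sd,
         synoptic_noise_scale = synoptic_noise_scale,
         local_noise_scale = local_noise_scale, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# ---- planted structure -----------------------------------------------------

LOCAL_VARS <- c("u", "v", "pres", "temp", "rh")
SYNOPTIC_VARS <- c("msl", "t850", "rh850", "clc")

# mode amplitudes in field units per unit score
.local_amplitudes <- list(u = c(8, 4), v = c(8, 4), pres = c(900, 350),
                          temp = c(6, 2.5), rh = c(20, 8))
.local_bin_noise <- c(u = 0.5, v = 0.5, pres = 30, temp = 0.3, rh = 2)
# synoptic mode amplitudes: peak per-cell field swing per unit score
# (scaled by each orthonormal mode's maximum loading at generation time)
.synoptic_amplitudes <- list(msl = c(400, 300, 220, 150),
                             t850 = c(3, 2.5, 2, 1.5),
                             rh850 = c(12, 9, 7, 5), clc = c(18, 13, 10, 7))
.synoptic_noise <- c(msl = 40, t850 = 0.4, rh850 = 3, clc = 4)

.mean_profile <- function(var, alt) {
  switch(var,
    bird = 0.25 + 1.1 * exp(-((alt - 500) / 1000)^2),
    u = 3 + 6 * alt / 3000,
    v = 1 + 2 * alt / 3000,
    pres = 101325 - 11.3 * alt,
    temp = 288 - 0.0065 * alt,
    rh = 70 - 0.005 * alt
  )
}

# Two planted vertical modes per variable, orthonormal under the quadrature
# weights: an intensity-like mode and an altitude-tilt mode.
.plant_vertical_modes <- function(alt, w) {
  shapes <- cbind(0.6 + 0.8 * exp(-alt / 1200), (alt - 1400) / 1500)
  b <- sweep(shapes, 1, sqrt(w), `*`)
  qd <- qr(b)
  q <- qr.Q(qd)
  modes <- sweep(q, 1, sqrt(w), `/`)
  # sign: intensity mode positive-mean, tilt mode increasing with altitude
  if (sum(w * modes[, 1]) < 0) modes[, 1] <- -modes[, 1]
  if (sum(w * modes[, 2] * (alt - mean(alt))) < 0) modes[, 2] <- -modes[, 2]
  modes
}

.mean_map <- function(var, grid) {
  lat <- grid$cell_lat
  lon <- grid$cell_lon
  switch(var,
    msl = 101325 - 12 * (lat - 40) + 4 * lon,
    t850 = 290 - 0.5 * (lat - 10) + 0.05 * lon,
    rh850 = 55 + 8 * sin(lat / 12) - 0.1 * lon,
    clc = 40 + 0.35 * (lat - 10)
  )
}

# Four planted spatial modes per synoptic variable: orthogonalized 2-D
# Gaussian bumps (QR on area-weight-scaled vectorized maps), so that they are
# smooth and recoverable by EOF.
.plant_spatial_modes <- function(var, grid, w) {
  centers <- switch(var,
    msl = cbind(c(-8, 55), c(3, 42), c(-15, 30), c(5, 62)),
    t850 = cbind(c(0, 50), c(-10, 38), c(6, 28), c(-16, 60)),
    rh850 = cbind(c(-4, 60), c(2, 35), c(-12, 45), c(7, 20)),
    clc = cbind(c(-2, 52), c(-14, 40), c(4, 32), c(-7, 22))
  )
  widths <- c(10, 11, 12, 9)
  raw <- sapply(1:4, function(k) {
    exp(-((grid$cell_lon - centers[1, k])^2 +
            (grid$cell_lat - centers[2, k])^2) / (2 * widths[k]^2))
  })
  b <- sweep(raw, 1, sqrt(w), `*`)
  q <- qr.Q(qr(b))
  modes <- sweep(q, 1, sqrt(w), `/`)
  for (k in 1:4) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  modes
}

# stationary AR(1) series with unit marginal variance
.ar1_series <- function(n, rho) {
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  s <- sqrt(1 - rho^2)
  for (t in 2:n) x[t] <- rho * x[t - 1] + s * e[t]
  x
}

# radar-specific phenology parameters: day-of-year Gaussian bumps for the
# two bird principal-component scores (gentle year-scale seasonality)
.plant_phenology <- function(radars) {
  n <- nrow(radars)
  i <- seq_len(n)
  rel <- if (n > 1) (i - 1) / (n - 1) else 0.5
  list(
    width = 60,
    pc1 = list(base = 0.3, amp_spring = 0.8 + 0.4 * rel,
               amp_autumn = 1.1 + 0.3 * rel,
               peak_spring = 95 + 2 * i, peak_autumn = 280 + 2 * i),
    pc2 = list(base = 0, amp_spring = rep(0.3, n), amp_autumn = rep(-0.15, n),
               peak_spring = 100 + 2 * i, peak_autumn = 285 + 2 * i)
  )
}

.phenology_value <- function(phen, pc, radar_idx, doy) {
  p <- phen[[pc]]
  w <- phen$width
  p$base +
    p$amp_spring[radar_idx] * exp(-(doy - p$peak_spring[radar_idx])^2 / (2 * w^2)) +
    p$amp_autumn[radar_idx] * exp(-(doy - p$peak_autumn[radar_idx])^2 / (2 * w^2))
}

# all season nights for a config
.season_nights <- function(config) {
  years <- config$start_year + seq_len(config$n_years) - 1
  months <- c(config$months_spring, config$months_autumn)
  days <- seq(as.Date(sprintf("%d-01-01", min(years))),
              as.Date(sprintf("%d-12-31", max(years))), by = "day")
  days[night_month(days) %in% months]
}

# grid cell index nearest to a lon/lat point
.nearest_cell <- function(grid, lon, lat) {
  i_lon <- sapply(lon, function(x) which.min(abs(grid$lon - x)))
  i_lat <- sapply(lat, function(x) which.min(abs(grid$lat - x)))
  (i_lat - 1L) * length(grid$lon) + i_lon
}

# ---- generation ------------------------------------------------------------

#' Generate synthetic weather (local profiles + synoptic fields)
#'
#' Synoptic fields are `mean map + sum_k score_k(t) * amplitude_k * mode_k +
#' noise` with orthonormal planted spatial modes and daily AR(1) unit-variance
#' scores. Local vertical profiles at each radar combine the synoptic scores
#' (weighted by the planted mode loading at the radar's grid cell) with two
#' planted vertical modes plus noise; cloudiness is clipped to `[0, 100]` %
#' and precipitation is non-negative. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `local` (per radar-night-slot profile panel of
#'   the five local variables plus cloud/precip scalars), `synoptic` (nightly
#'   fields per variable), and `truth` (the planted structure so far).
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, .generate_weather_impl(config))
}

.generate_weather_impl <- function(config) {
  grid <- config$grid
  alt <- config$altitudes
  w_alt <- quadrature_weights(length(alt))
  w_area <- grid_area_weights(grid)
  radars <- config$radars
  n_rad <- nrow(radars)
  nights <- .season_nights(config)
  n_nights <- length(nights)
  if (n_nights == 0) stop("configuration yields no nights")

  # daily AR(1) scores over the full calendar span (so that lagged nightly
  # values are well-defined even across season gaps)
  days <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
              as.Date(sprintf("%d-12-31", config$start_year + config$n_years - 1)),
              by = "day")
  scores_daily <- array(0, dim = c(length(days), 4, length(SYNOPTIC_VARS)),
                        dimnames = list(NULL, NULL, SYNOPTIC_VARS))
  for (v in seq_along(SYNOPTIC_VARS)) {
    for (k in 1:4) scores_daily[, k, v] <- .ar1_series(length(days), config$ar_coef)
  }
  night_day_idx <- match(nights, days)

  # synoptic fields
  spatial_modes <- lapply(SYNOPTIC_VARS, function(v) .plant_spatial_modes(v, grid, w_area))
  names(spatial_modes) <- SYNOPTIC_VARS
  fields <- list()
  for (v in SYNOPTIC_VARS) {
    amp <- .synoptic_amplitudes[[v]] / apply(abs(spatial_modes[[v]]), 2, max)
    s <- scores_daily[night_day_idx, , v, drop = TRUE]
    f <- s %*% t(sweep(spatial_modes[[v]], 2, amp, `*`))
    f <- sweep(f, 2, .mean_map(v, grid), `+`)
    ns <- .synoptic_noise[[v]] * config$synoptic_noise_scale
    if (ns > 0) f <- f + matrix(rnorm(length(f), 0, ns), nrow(f))
    fields[[v]] <- f
  }

  # local panel: radars x nights x 3 slots
  meta <- data.frame(
    radar = rep(radars$id, each = n_nights * 3L),
    night = rep(rep(nights, each = 3L), times = n_rad),
    slot = rep(c("early", "mid", "late"), times = n_rad * n_nights),
    stringsAsFactors = FALSE
  )
  n_loc <- nrow(meta)
  radar_idx <- match(meta$radar, radars$id)
  day_idx <- night_day_idx[match(meta$night, nights)]

  # planted vertical modes (shared shapes across variables; per-variable
  # amplitudes distinguish them) and mode loadings at radar locations
  vmodes <- .plant_vertical_modes(alt, w_alt)
  cells_r <- .nearest_cell(grid, radars$lon, radars$lat)
  loading_at <- function(var, k) {
    l <- spatial_modes[[var]][cells_r, k]
    r <- sqrt(mean(l^2))
    if (r < 1e-12) rep(1, length(l)) else l / r
  }
  coupling <- list(u = list(var = "msl", k = 1), v = list(var = "msl", k = 2),
                   pres = list(var = "msl", k = 1),
                   temp = list(var = "t850", k = 1),
                   rh = list(var = "rh850", k = 1))

  lns <- config$local_noise_scale
  amp1 <- array(NA_real_, dim = c(n_loc, length(LOCAL_VARS)),
                dimnames = list(NULL, LOCAL_VARS))
  amp2 <- amp1
  profiles <- list()
  for (v in LOCAL_VARS) {
    cp <- coupling[[v]]
    l_r <- loading_at(cp$var, cp$k)
    syn <- scores_daily[cbind(day_idx, rep(cp$k, n_loc),
                              rep(match(cp$var, SYNOPTIC_VARS), n_loc))]
    # nightly amplitude + small slot-level jitter
    a1_n <- 0.75 * syn * l_r[radar_idx] + lns * 0.66 * .night_noise(meta)
    a2_n <- .night_noise(meta)
    a1 <- a1_n + lns * 0.25 * rnorm(n_loc)
    a2 <- a2_n + lns * 0.25 * rnorm(n_loc)
    amp1[, v] <- a1
    amp2[, v] <- a2
    a <- .local_amplitudes[[v]]
    p <- outer(rep(1, n_loc), .mean_profile(v, alt)) +
      (a1 * a[1]) %*% t(vmodes[, 1]) + (a2 * a[2]) %*% t(vmodes[, 2])
    bn <- .local_bin_noise[[v]] * lns
    if (bn > 0) p <- p + matrix(rnorm(length(p), 0, bn), nrow(p))
    profiles[[v]] <- p
  }

  clc_score <- scores_daily[cbind(day_idx, rep(1L, n_loc),
                                  rep(match("clc", SYNOPTIC_VARS), n_loc))]
  l_clc <- loading_at("clc", 1)
  cloud <- 55 + 16 * clc_score * l_clc[radar_idx] +
    lns * (10 * .night_noise(meta) + 4 * rnorm(n_loc))
  cloud <- pmin(pmax(cloud, 0), 100)
  rh_score <- scores_daily[cbind(day_idx, rep(1L, n_loc),
                                 rep(match("rh850", SYNOPTIC_VARS), n_loc))]
  l_rh <- loading_at("rh850", 1)
  precip <- pmax(0, 1.8 * (0.7 * rh_score * l_rh[radar_idx] +
                             lns * 0.7 * .night_noise(meta)) - 1.6)

  truth <- structure(
    list(spatial_modes = spatial_modes,
         synoptic_amplitudes = .synoptic_amplitudes,
         vertical_modes = vmodes,
         local_amplitudes = .local_amplitudes,
         score_days = days, scores_daily = scores_daily,
         local_amp1 = amp1, local_amp2 = amp2,
         ar_coef = config$ar_coef,
         effect_sizes = config$effect_sizes, noise_sd = config$noise_sd),
    class = "planted_truth"
  )

  list(
    local = list(meta = meta, profiles = profiles,
                 cloud = cloud, precip = precip, altitudes = alt),
    synoptic = list(nights = nights, grid = grid, fields = fields),
    truth = truth
  )
}

# nightly (slot-shared) standard normal draws for a (radar, night, slot) meta
.night_noise <- function(meta) {
  key <- paste(meta$radar, meta$night)
  uk <- unique(key)
  rnorm(length(uk))[match(key, uk)]
}

#' Generate synthetic bird-density profiles
#'
#' Builds the planted anomaly response: the standardized anomaly of the
#' intensity score is `beta * wind_support_now + gamma * mean_headwind_3n +
#' delta * mean_synoptic_score_3n + noise` (each predictor standardized per
#' season), the altitude score responds to the altitude-tilt wind mode. The
#' scores are mapped through the planted phenology and vertical modes into
#' log-density profiles, sampled at the nine nightly time points with
#' measurement noise, converted back to densities (`10^x - 1`, floored at 0),
#' contaminated with insect events at `insect_rate` (low airspeed), and
#' thinned by dropping altitude bins at `missing_rate`.
#'
#' @param config A [synthetic_config()].
#' @param weather Output of [generate_weather()] for the same config.
#' @param truth The `truth` element of the same weather object.
#' @return List with `raw` (long VPTS-style data.frame: radar, datetime,
#'   height, dens, eta, airspeed), `truth_rows` (per radar-night-slot planted
#'   anomalies and insect flags), `latent` (noise-free log-density
#'   [profile_panel()]), and the completed `truth`.
#' @export
generate_bird_profiles <- function(config, weather, truth = weather$truth) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 1L, .generate_birds_impl(config, weather, truth))
}

.generate_birds_impl <- function(config, weather, truth) {
  alt <- config$altitudes
  w_alt <- quadrature_weights(length(alt))
  meta <- weather$local$meta
  n <- nrow(meta)
  radars <- config$radars
  radar_idx <- match(meta$radar, radars$id)
  season <- night_season(meta$night, config$months_spring, config$months_autumn)
  doy <- doy_index(meta$night)

  # wind support: weighted-mean wind projected on the seasonal migration
  # direction (NE-bound in spring, SW-bound in autumn)
  m1 <- sapply(LOCAL_VARS[1:2], function(v) {
    sum(w_alt * truth$vertical_modes[, 1]) / sum(w_alt) *
      .local_amplitudes[[v]][1]
  })
  mean_u <- sum(w_alt * .mean_profile("u", alt)) / sum(w_alt) +
    truth$local_amp1[, "u"] * m1[["u"]]
  mean_v <- sum(w_alt * .mean_profile("v", alt)) / sum(w_alt) +
    truth$local_amp1[, "v"] * m1[["v"]]
  dir_x <- ifelse(season == "spring", 1, -1) * sqrt(0.5)
  dir_y <- dir_x
  ws <- dir_x * mean_u + dir_y * mean_v
  ws2 <- dir_x * truth$local_amp2[, "u"] + dir_y * truth$local_amp2[, "v"]

  std_by_season <- function(x) {
    for (s in unique(season)) {
      i <- season == s
      mu <- mean(x[i], na.rm = TRUE)
      sg <- stats::sd(x[i], na.rm = TRUE)
      x[i] <- if (is.na(sg) || sg < 1e-12) 0 else (x[i] - mu) / sg
    }
    x[is.na(x)] <- 0
    x
  }
  ws_std <- std_by_season(ws)
  ws2_std <- std_by_season(ws2)

  # mean headwind over the previous three nights (nightly averages)
  nt <- data.table::data.table(radar = meta$radar, night = meta$night, ws = ws)
  nightly <- nt[, .(ws_n = mean(ws)), by = .(radar, night)]
  lagmat <- sapply(1:3, function(j) {
    m <- merge(nightly[, .(radar, night)],
               nightly[, .(radar, night = night + j, ws_l = ws_n)],
               by = c("radar", "night"), all.x = TRUE, sort = FALSE)
    m[match(paste(nightly$radar, nightly$night), paste(m$radar, m$night)), ws_l]
  })
  hw_n <- -rowMeans(lagmat, na.rm = TRUE)  # headwind = negative support
  hw_n[is.nan(hw_n)] <- NA
  hw3 <- hw_n[match(paste(meta$radar, meta$night),
                    paste(nightly$radar, nightly$night))]
  hw3_std <- std_by_season(hw3)

  # lagged synoptic driver: mean over the previous 3 calendar days of the
  # second temperature-mode score (not coupled to local wind)
  day_idx <- match(meta$night, truth$score_days)
  s_t2 <- truth$scores_daily[, 2, "t850"]
  syn3 <- (s_t2[day_idx - 1] + s_t2[day_idx - 2] + s_t2[day_idx - 3]) / 3
  syn3[is.na(syn3)] <- 0
  syn3_std <- std_by_season(syn3)

  es <- config$effect_sizes
  z1 <- es$beta_wind_now * ws_std + es$gamma_headwind_lag * hw3_std +
    es$delta_synoptic_lag * syn3_std + config$noise_sd * rnorm(n)
  z2 <- 0.5 * es$beta_wind_now * ws2_std + config$noise_sd * rnorm(n)

  phen <- .plant_phenology(radars)
  score1 <- .phenology_value(phen, "pc1", radar_idx, doy) + z1
  score2 <- .phenology_value(phen, "pc2", radar_idx, doy) + z2

  bird_modes <- .plant_vertical_modes(alt, w_alt)
  latent <- outer(rep(1, n), .mean_profile("bird", alt)) +
    score1 %*% t(bird_modes[, 1]) + score2 %*% t(bird_modes[, 2])

  # insect contamination: event-level airspeed from a low-speed component
  insect <- runif(n) < config$insect_rate
  air_event <- ifelse(insect, rnorm(n, 2, 0.5), rnorm(n, 10, 1.5))
  air_event <- pmax(air_event, 0.2)

  # nine sub-nightly raw profiles: latent + measurement noise, inverse-log,
  # floored at zero density
  nbin <- length(alt)
  sub_list <- vector("list", 3L)
  clipped <- 0L
  for (s in 1:3) {
    x <- latent + matrix(rnorm(n * nbin, 0, config$profile_noise_sd), n)
    dens <- log_inverse(x)
    clipped <- clipped + sum(dens < 0)
    dens[dens < 0] <- 0
    sub_list[[s]] <- dens
  }
  if (clipped / (3 * n * nbin) > 0.25) {
    warning("more than 25% of density cells clipped at zero; ",
            "check effect sizes and phenology scale")
  }

  slot_hour <- SLOT_HOURS[meta$slot]
  base_time <- as.POSIXct(paste(meta$night + (meta$slot == "late"),
                                sprintf("%02d:00:00", slot_hour)), tz = "UTC")
  keep_p <- if (config$missing_rate > 0) {
    matrix(runif(3L * n * nbin) >= config$missing_rate, 3L * n)
  } else {
    matrix(TRUE, 3L * n, nbin)
  }
  raw <- vector("list", 3L)
  for (s in 1:3) {
    keep <- keep_p[(s - 1L) * n + seq_len(n), , drop = FALSE]
    idx <- which(keep, arr.ind = TRUE)
    dens <- sub_list[[s]][keep]
    raw[[s]] <- data.frame(
      radar = meta$radar[idx[, 1]],
      datetime = base_time[idx[, 1]] + (s - 1L) * 900,
      height = alt[idx[, 2]],
      dens = dens,
      eta = dens * 11,
      airspeed = air_event[idx[, 1]] + rnorm(nrow(idx), 0, 0.3)
    )
  }
  raw <- do.call(rbind, raw)
  raw <- raw[order(raw$radar, raw$datetime, raw$height), ]
  rownames(raw) <- NULL

  truth$phenology <- phen
  truth$bird_modes <- bird_modes
  truth_rows <- data.frame(
    radar = meta$radar, night = meta$night, slot = meta$slot,
    season = season, z1 = z1, z2 = z2, score1 = score1, score2 = score2,
    ws_std = ws_std, hw3_std = hw3_std, syn3_std = syn3_std, insect = insect
  )
  list(
    raw = raw,
    truth_rows = truth_rows,
    latent = profile_panel(meta, latent),
    truth = truth
  )
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_weather()] and [generate_bird_profiles()] and bundles the
#' result; optionally writes everything to disk (VPTS-style CSV for raw
#' profiles, CSV matrices plus a JSON sidecar for the gridded fields, CSVs
#' for local weather, JSON for the planted truth, and a manifest carrying the
#' seed and a config fingerprint).
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory (created if needed).
#' @return Object of class `mig_dataset`: list with `config`, `radars`,
#'   `raw`, `local`, `synoptic`, `truth`, `truth_rows`, `latent`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  wx <- generate_weather(config)
  birds <- generate_bird_profiles(config, wx)
  ds <- structure(
    list(config = config, radars = config$radars, raw = birds$raw,
         local = wx$local, synoptic = wx$synoptic, truth = birds$truth,
         truth_rows = birds$truth_rows, latent = birds$latent),
    class = "mig_dataset"
  )
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.mig_dataset <- function(x, ...) {
  cat(sprintf(
    "<mig_dataset> %d radars, %d nights (%d year(s)), %d raw rows, seed %d\n",
    nrow(x$radars), length(x$synoptic$nights), x$config$n_years,
    nrow(x$raw), x$config$seed
  ))
  invisible(x)
}
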