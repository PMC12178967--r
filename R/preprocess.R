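# Preprocessing of raw radar profiles: unit conversion, log transform,
# hourly slot averaging with the <5-bin completeness filter, vertical
# interpolation to the standard grid, and insect-event exclusion.

#' Convert volumetric reflectivity to bird density
#'
#' Divides volumetric reflectivity eta (cm^2 km^-3) by the assumed average
#' radar cross section of a single bird, 11 cm^2, giving birds per km^3.
#'
#' @param eta Non-negative numeric vector of volumetric reflectivities.
#' @param rcs Radar cross section per bird in cm^2 (default 11).
#' @return Bird density in individuals km^-3.
#' @export
reflectivity_to_density <- function(eta, rcs = 11) {
  if (any(eta < 0, na.rm = TRUE)) stop("reflectivity must be non-negative")
  eta / rcs
}

#' Log-transform bird densities
#'
#' `log_transform()` maps density x (ind km^-3) to log10(x + 1), reducing the
#' strong right skew of nightly bird densities while keeping 0 at 0.
#' `log_inverse()` is its exact inverse.
#'
#' @param x Non-negative densities (for `log_transform`) or log-densities
#'   (for `log_inverse`).
#' @return Transformed values.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("density must be non-negative")
  log10(x + 1)
}

#' @rdname log_transform
#' @export
log_inverse <- function(x) 10^x - 1

# Classify a UTC timestamp into (night, slot, sub-index); NA for timestamps
# outside the nine defined sampling points.
.parse_sampling_times <- function(datetime) {
  dt <- as.POSIXct(datetime, tz = "UTC")
  lt <- as.POSIXlt(dt, tz = "UTC")
  hour <- lt$hour
  min <- lt$min
  ok <- (hour %in% SLOT_HOURS) & (min %in% SUB_MINUTES) & (lt$sec == 0)
  slot <- rep(NA_character_, length(dt))
  slot[ok & hour == 20L] <- "early"
  slot[ok & hour == 23L] <- "mid"
  slot[ok & hour == 2L] <- "late"
  night <- as.Date(dt, tz = "UTC")
  # profiles sampled at 02:xx belong to the night labelled by the previous date
  night[!is.na(slot) & slot == "late"] <- night[!is.na(slot) & slot == "late"] - 1L
  list(night = night, slot = slot, sub = min %/% 15L, ok = ok)
}

#' Build nightly vertical profiles from raw sub-nightly profiles
#'
#' Raw profiles sampled at the nine nightly time points (20:00, 20:15, 20:30,
#' 23:00, 23:15, 23:30, 02:00, 02:15, 02:30 UTC) are averaged hourly (h+0,
#' h+15, h+30) into up to three profiles per radar and night (early, mid,
#' late). Sub-profiles with fewer than `min_bins` valid altitude bins are
#' discarded before averaging; averages ignore invalid bins. Surviving slot
#' profiles are linearly interpolated onto the standard 13-level grid, without
#' extrapolation beyond the valid altitude range (bins outside it stay
#' masked). Densities are log-transformed (log10(x+1)) before averaging.
#'
#' @param raw data.frame with columns `radar`, `datetime` (UTC, POSIXct or
#'   ISO-8601 string), `height` (m) and `dens` (ind km^-3); optionally `eta`
#'   (used via [reflectivity_to_density()] when `dens` is absent) and
#'   `airspeed` (m s^-1, averaged per radar-night-slot event).
#' @param altitudes Target altitude grid; defaults to [mig_altitudes()].
#' @param min_bins Minimum number of valid altitude bins for a sub-profile to
#'   enter its slot average (default 5).
#' @return A [profile_panel()] of log-density profiles with meta columns
#'   `radar`, `night`, `slot`, `airspeed` (NA when unavailable) and
#'   `n_subprofiles`.
#' @export
build_nightly_profiles <- function(raw, altitudes = mig_altitudes(),
                                   min_bins = 5) {
  raw <- as.data.frame(raw)
  if (!"dens" %in% names(raw)) {
    if (!"eta" %in% names(raw)) stop("raw data needs a 'dens' or 'eta' column")
    raw$dens <- reflectivity_to_density(raw$eta)
  }
  tm <- .parse_sampling_times(raw$datetime)
  if (any(!tm$ok)) {
    warning(sprintf("%d rows with timestamps outside the 9 sampling points dropped",
                    sum(!tm$ok)))
  }
  dt <- data.table::data.table(
    radar = as.character(raw$radar),
    night = tm$night, slot = tm$slot, sub = tm$sub,
    height = raw$height,
    logdens = log_transform(raw$dens),
    airspeed = if ("airspeed" %in% names(raw)) raw$airspeed else NA_real_
  )[tm$ok & !is.na(raw$dens)]

  # completeness filter per sub-profile
  dt[, nbins := .N, by = .(radar, night, slot, sub)]
  dt <- dt[nbins >= min_bins]
  if (nrow(dt) == 0L) stop("no sub-profile passes the completeness filter")

  # hourly (slot) average over sub-profiles, ignoring invalid bins
  slot_avg <- dt[, .(
    logdens = mean(logdens),
    airspeed = mean(airspeed)
  ), by = .(radar, night, slot, height)]
  n_subs <- dt[, .(n_subprofiles = length(unique(sub))),
               by = .(radar, night, slot)]

  # linear interpolation to the standard grid, masked outside the valid range
  interp <- slot_avg[, {
    if (.N == 1L) {
      v <- rep(NA_real_, length(altitudes))
      v[which.min(abs(altitudes - height))] <- logdens
    } else {
      v <- stats::approx(height, logdens, xout = altitudes, rule = 1)$y
    }
    list(alt = altitudes, value = v, airspeed = mean(airspeed))
  }, by = .(radar, night, slot)]

  meta_dt <- unique(interp[, .(radar, night, slot,
                               airspeed = round(airspeed, 10))])
  meta_dt <- merge(meta_dt, n_subs, by = c("radar", "night", "slot"))
  slot_order <- c(early = 1L, mid = 2L, late = 3L)
  data.table::setorder(meta_dt, radar, night)
  meta_dt <- meta_dt[order(radar, night, slot_order[slot])]

  values <- matrix(NA_real_, nrow(meta_dt), length(altitudes))
  key_all <- paste(interp$radar, interp$night, interp$slot)
  key_meta <- paste(meta_dt$radar, meta_dt$night, meta_dt$slot)
  row_of <- match(key_all, key_meta)
  values[cbind(row_of, match(interp$alt, altitudes))] <- interp$value

  meta <- as.data.frame(meta_dt)
  meta$night <- as.Date(meta$night)
  profile_panel(meta, values, !is.na(values), altitudes)
}

#' Classify radar events as bird- or insect-dominated
#'
#' Fits a univariate Gaussian mixture to event-level mean airspeeds (one
#' event = one radar-night-slot profile). If a 2-component mixture is
#' preferred over 1 component by BIC, events assigned to the lower-mean
#' component are labelled `insect` (insects are slow flyers, typically
#' ~2 m/s, versus ~10 m/s ground-relative airspeeds for migrating birds);
#' otherwise everything is labelled `bird`.
#'
#' @param panel A [profile_panel()] whose meta has an `airspeed` column.
#' @param min_events Minimum number of events required to attempt the fit.
#' @return Factor of length `nrow(panel$meta)` with levels `bird`, `insect`.
#' @export
classify_insect_events <- function(panel, min_events = 20) {
  stop_if_not_panel(panel)
  air <- panel$meta$airspeed
  labels <- factor(rep("bird", length(air)), levels = c("bird", "insect"))
  if (is.null(air) || all(is.na(air))) {
    warning("no airspeed available; insect classification skipped")
    return(labels)
  }
  ok <- !is.na(air)
  if (sum(ok) < min_events) {
    warning("fewer events than 'min_events'; insect classification skipped")
    return(labels)
  }
  fit <- mclust::Mclust(air[ok], G = 1:2, modelNames = c("E", "V"),
                        verbose = FALSE)
  if (!is.null(fit) && fit$G == 2L) {
    low <- which.min(fit$parameters$mean)
    idx <- which(ok)[fit$classification == low]
    labels[idx] <- "insect"
  }
  labels
}

#' Remove insect-dominated events from a panel
#'
#' @param panel A [profile_panel()].
#' @param labels Optional factor from [classify_insect_events()]; computed
#'   when omitted.
#' @return The panel restricted to bird events.
#' @export
filter_insects <- function(panel, labels = NULL) {
  stop_if_not_panel(panel)
  if (is.null(labels)) labels <- classify_insect_events(panel)
  panel_subset(panel, labels == "bird")
}
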