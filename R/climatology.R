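# Day-of-year climatologies for de-trending: smoothed climatological mean and
# standard deviation on a circular 366-day calendar, plus the astronomical
# time features (solar declination, time-of-day angle).
#
# The mean is estimated by local-linear kernel regression (Gaussian kernel,
# circular day-of-year distance). Local-linear rather than Nadaraya-Watson
# smoothing matters here because migration data exist only inside the two
# season windows: at a window edge the kernel becomes one-sided and a
# zeroth-order smoother picks up first-order bias from the phenology slope,
# while the local-linear estimator stays unbiased to first order.

# kernel moment matrices for a bandwidth, cached per session
.clim_cache <- new.env(parent = emptyenv())

.clim_kernels <- function(bandwidth) {
  key <- sprintf("bw_%g", bandwidth)
  if (!is.null(.clim_cache[[key]])) return(.clim_cache[[key]])
  d <- outer(1:366, 1:366, `-`)
  d <- ((d + 183) %% 366) - 183  # circular signed distance
  k0 <- exp(-0.5 * (d / bandwidth)^2)
  out <- list(k0 = k0, k1 = k0 * d, k2 = k0 * d * d)
  .clim_cache[[key]] <- out
  out
}

# per-day-of-year sums of 1, x, x^2 as 366-length vectors
.doy_aggregates <- function(x, doy) {
  n <- tabulate(doy, nbins = 366)
  s <- rep(0, 366)
  q <- rep(0, 366)
  sx <- rowsum(cbind(x, x * x), doy)
  idx <- as.integer(rownames(sx))
  s[idx] <- sx[, 1]
  q[idx] <- sx[, 2]
  list(n = n, s = s, q = q)
}

#' Fit a day-of-year climatology
#'
#' Estimates the climatological mean `mu_d` and standard deviation `sigma_d`
#' of a score series for every day of a 366-day circular calendar, by
#' Gaussian-kernel smoothing in day-of-year distance (local-linear for the
#' mean, kernel-weighted residual spread for the sd). `sigma_d` is floored at
#' `sigma_floor`.
#'
#' @param x Numeric score series.
#' @param dates Dates (or anything coercible via `as.Date`) matching `x`.
#' @param bandwidth Kernel bandwidth in days (default 15).
#' @param sigma_floor Lower bound for `sigma_d` (default 1e-6).
#' @param name Optional series name.
#' @return Object of class `climatology` with `mu` and `sigma` (366 values).
#' @export
fit_climatology <- function(x, dates, bandwidth = 15, sigma_floor = 1e-6,
                            name = "") {
  ok <- !is.na(x)
  x <- x[ok]
  if (length(x) == 0L) stop("empty series")
  doy <- doy_index(as.Date(dates)[ok])
  ag <- .doy_aggregates(x, doy)
  kk <- .clim_kernels(bandwidth)
  m0 <- as.vector(kk$k0 %*% ag$n)
  m1 <- as.vector(kk$k1 %*% ag$n)
  m2 <- as.vector(kk$k2 %*% ag$n)
  b0 <- as.vector(kk$k0 %*% ag$s)
  b1 <- as.vector(kk$k1 %*% ag$s)
  den <- m0 * m2 - m1 * m1
  mu <- ifelse(den > 1e-10 * pmax(m0 * m2, 1e-300),
               (m2 * b0 - m1 * b1) / den,
               b0 / pmax(m0, 1e-300))
  # sigma from residuals against each observation's own-day mean, so that a
  # steep seasonal slope within the kernel window does not inflate the sd
  r2 <- (x - mu[doy])^2
  agr <- .doy_aggregates(r2, doy)
  v <- as.vector(kk$k0 %*% agr$s) / pmax(m0, 1e-300)
  sigma <- pmax(sqrt(pmax(v, 0)), sigma_floor)
  structure(
    list(name = name, mu = mu, sigma = sigma, bandwidth = bandwidth,
         sigma_floor = sigma_floor, n = length(x)),
    class = "climatology"
  )
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> %s: n = %d, bandwidth = %g d, mu in [%.3g, %.3g]\n",
              if (nzchar(x$name)) x$name else "(unnamed)", x$n, x$bandwidth,
              min(x$mu), max(x$mu)))
  invisible(x)
}

#' Climatological mean and sd for given dates
#'
#' @param clim A `climatology`.
#' @param dates Dates.
#' @return For `clim_mean`/`clim_sd`, numeric vectors.
#' @export
clim_mean <- function(clim, dates) clim$mu[doy_index(dates)]

#' @rdname clim_mean
#' @export
clim_sd <- function(clim, dates) clim$sigma[doy_index(dates)]

#' Standardized anomalies relative to a climatology
#'
#' `standardize_anomaly()` maps a score x on date d to
#' `z = (x - mu_d) / sigma_d`; `destandardize_anomaly()` is the exact
#' inverse. `anomaly()` returns the unstandardized anomaly `x - mu_d` (used
#' for the weather predictors, which the feature design leaves unscaled).
#'
#' @param x Scores (or standardized anomalies for the inverse).
#' @param dates Matching dates.
#' @param clim A `climatology`.
#' @return Numeric vector.
#' @export
standardize_anomaly <- function(x, dates, clim) {
  d <- doy_index(dates)
  (x - clim$mu[d]) / clim$sigma[d]
}

#' @rdname standardize_anomaly
#' @export
destandardize_anomaly <- function(x, dates, clim) {
  d <- doy_index(dates)
  x * clim$sigma[d] + clim$mu[d]
}

#' @rdname standardize_anomaly
#' @export
anomaly <- function(x, dates, clim) {
  x - clim$mu[doy_index(dates)]
}

# Day-of-year climatological mean for every cell of a gridded field.
# X is nights x cells; returns a 366 x cells matrix of local-linear smoothed
# means (same estimator as fit_climatology, vectorized across cells). Rows
# outside `doys_out` are left NA; columns of the kernel matrices are
# restricted to the days that actually carry data, which keeps the matrix
# products proportional to the season-window length rather than the year.
field_climatology <- function(x, dates, bandwidth = 15, doys_out = 1:366) {
  doy <- doy_index(dates)
  kk <- .clim_kernels(bandwidth)
  sx <- rowsum(x, doy)
  days_in <- as.integer(rownames(sx))
  n_d <- tabulate(doy, nbins = 366)[days_in]
  k0 <- kk$k0[doys_out, days_in, drop = FALSE]
  k1 <- kk$k1[doys_out, days_in, drop = FALSE]
  k2 <- kk$k2[doys_out, days_in, drop = FALSE]
  m0 <- as.vector(k0 %*% n_d)
  m1 <- as.vector(k1 %*% n_d)
  m2 <- as.vector(k2 %*% n_d)
  b0 <- k0 %*% sx
  b1 <- k1 %*% sx
  den <- m0 * m2 - m1 * m1
  use_ll <- den > 1e-10 * pmax(m0 * m2, 1e-300)
  sub <- (m2 * b0 - m1 * b1) / ifelse(use_ll, den, 1)
  mu_nw <- b0 / pmax(m0, 1e-300)
  sub[!use_ll, ] <- mu_nw[!use_ll, ]
  mu <- matrix(NA_real_, 366, ncol(x))
  mu[doys_out, ] <- sub
  mu
}

# Anomalies of a gridded field panel relative to a 366 x cells climatology.
field_anomalies <- function(x, dates, mu) {
  x - mu[doy_index(dates), , drop = FALSE]
}

#' Solar declination
#'
#' Standard astronomical approximation of the sun's declination (degrees) for
#' a date; used as a smooth, physically meaningful proxy for day of year.
#'
#' @param dates Dates.
#' @return Declination in degrees (about -23.44 to +23.44).
#' @export
solar_declination <- function(dates) {
  doy <- doy_index(dates)
  -23.44 * cos(2 * pi * (doy + 10) / 365.2422)
}

#' Time-of-day angle
#'
#' Maps a UTC timestamp to the angle `2 * pi * seconds_since_midnight / 86400`
#' (radians), encoding the rotation of the Earth relative to fixed stars.
#'
#' @param datetime POSIXct timestamps (UTC).
#' @return Angle in radians, in `[0, 2 * pi)`.
#' @export
time_angle <- function(datetime) {
  lt <- as.POSIXlt(datetime, tz = "UTC")
  secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  2 * pi * secs / 86400
}
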