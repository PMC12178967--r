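# Shared conventions: altitude grid, night/slot timing, day-of-year calendar.

#' Standard altitude grid
#'
#' The 13 altitude levels (m above ground) used throughout: 0 to 3000 m in
#' 250 m steps, matching the vertical axis of the numerical weather data.
#'
#' @return Numeric vector of 13 altitudes in metres.
#' @export
mig_altitudes <- function() seq(0, 3000, by = 250)

# The nine sub-nightly sampling times (UTC "HH:MM"), three per slot.
SLOT_HOURS <- c(early = 20L, mid = 23L, late = 2L)
SUB_MINUTES <- c(0L, 15L, 30L)

#' Trapezoidal quadrature weights
#'
#' Weights for the discretized functional inner product on an equally spaced
#' grid, normalized to sum to the number of grid points so that uniform
#' weights (ordinary PCA) and trapezoid weights share the same scale.
#'
#' @param n Number of grid points.
#' @return Numeric vector of length `n` summing to `n`.
#' @export
quadrature_weights <- function(n) {
  stopifnot(n >= 2)
  w <- c(0.5, rep(1, n - 2), 0.5)
  w * n / sum(w)
}

# Day-of-year index on a fixed 366-day calendar (Feb 29 = 60), so that a
# given month/day always maps to the same index across leap and common years.
doy_index <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  cum <- cumsum(c(0L, 31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L))
  cum[lt$mon + 1L] + lt$mday
}

night_year <- function(nights) as.integer(format(as.Date(nights), "%Y"))
night_month <- function(nights) as.integer(format(as.Date(nights), "%m"))

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Polynomial rolling hash of a string (mod 2^31 - 1); used only as a config
# fingerprint in dataset manifests.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_panel <- function(x) {
  if (!inherits(x, "profile_panel")) stop("expected a 'profile_panel' object")
  invisible(x)
}

#' Construct a vertical profile panel
#'
#' A profile panel holds one vertical profile per row: a metadata table
#' (radar, night, slot, ...), a numeric value matrix (rows x altitudes) and a
#' logical validity mask of the same shape.
#'
#' @param meta data.frame with at least columns `radar`, `night`, `slot`.
#' @param values Numeric matrix, one row per profile, one column per altitude.
#' @param valid Logical matrix of the same shape; `FALSE` marks missing bins.
#' @param altitudes Altitude grid (m); defaults to [mig_altitudes()].
#' @return An object of class `profile_panel`.
#' @export
profile_panel <- function(meta, values, valid = NULL,
                          altitudes = mig_altitudes()) {
  values <- as.matrix(values)
  stopifnot(nrow(meta) == nrow(values), ncol(values) == length(altitudes))
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(identical(dim(valid), dim(values)))
  structure(
    list(meta = as.data.frame(meta), values = values,
         valid = valid, altitudes = altitudes),
    class = "profile_panel"
  )
}

#' @export
print.profile_panel <- function(x, ...) {
  cat(sprintf(
    "<profile_panel> %d profiles x %d altitude bins (%g-%g m), %d radars\n",
    nrow(x$values), length(x$altitudes), min(x$altitudes), max(x$altitudes),
    length(unique(x$meta$radar))
  ))
  invisible(x)
}

#' @export
dim.profile_panel <- function(x) dim(x$values)

# Row subset of a panel.
panel_subset <- function(panel, idx) {
  profile_panel(panel$meta[idx, , drop = FALSE],
                panel$values[idx, , drop = FALSE],
                panel$valid[idx, , drop = FALSE],
                panel$altitudes)
}

# Season of a night given the month windows of the study design.
night_season <- function(nights, months_spring = 2:5, months_autumn = 7:11) {
  m <- night_month(nights)
  ifelse(m %in% months_spring, "spring",
         ifelse(m %in% months_autumn, "autumn", NA_character_))
}
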