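# Empirical orthogonal functions of gridded synoptic anomaly fields.
# Area-weighted (cos-latitude) PCA of the (time x space) anomaly matrix,
# computed through the time-by-time Gram matrix, which is much smaller than
# the space dimension on a 0.5-degree grid.

#' Define a regular longitude-latitude grid
#'
#' Cells are ordered longitude-fastest: cell = (i_lat - 1) * n_lon + i_lon.
#'
#' @param lon,lat Numeric vectors of grid-line coordinates (degrees).
#' @return A list with `lon`, `lat`, `n_cells`, and per-cell coordinate
#'   vectors `cell_lon`, `cell_lat`.
#' @export
make_grid <- function(lon = seq(-20, 10, by = 0.5),
                      lat = seq(10, 70, by = 0.5)) {
  list(lon = lon, lat = lat, n_cells = length(lon) * length(lat),
       cell_lon = rep(lon, times = length(lat)),
       cell_lat = rep(lat, each = length(lon)))
}

# cos-latitude area weights, normalized to mean 1.
grid_area_weights <- function(grid) {
  w <- cos(grid$cell_lat * pi / 180)
  w / mean(w)
}

#' Fit an EOF basis to nightly anomaly fields
#'
#' Decomposes a (nights x cells) anomaly matrix into orthonormal spatial
#' modes under the cos-latitude-weighted inner product, with one score per
#' mode and night. Mode signs are fixed so that each mode's largest-magnitude
#' loading is positive. Fields are centered in time before decomposition (the
#' stored `mean_map` is usually near zero when the input is already an
#' anomaly from a day-of-year climatology).
#'
#' @param x Numeric matrix, nights x cells, on the grid `grid`.
#' @param grid Grid from [make_grid()].
#' @param n_components Number of modes to retain (default 4).
#' @param variable Optional variable name.
#' @return An object of class `eof_basis` with `mean_map`, `modes`
#'   (cells x n_components), `weights`, `explained`.
#' @export
fit_eof <- function(x, grid = make_grid(), n_components = 4, variable = "") {
  x <- as.matrix(x)
  if (ncol(x) != grid$n_cells) stop("field size does not match the grid")
  n <- nrow(x)
  if (n < n_components) stop("fewer nights than components")
  w <- grid_area_weights(grid)
  mu <- colMeans(x)
  sw <- sqrt(w)
  # B = centered fields scaled by sqrt(w); Gram in time space
  # (recycled-vector arithmetic: sweep() is an aperm bottleneck at this size)
  b <- (x - rep(mu, each = n)) * rep(sw, each = n)
  g <- tcrossprod(b)
  total <- sum(diag(g)) / (n - 1)
  if (total < 1e-12) stop("fields are constant; no variance to decompose")
  eg <- eigen(g / (n - 1), symmetric = TRUE)
  lambda <- pmax(eg$values[seq_len(n_components)], 0)
  if (any(lambda < 1e-12 * total)) {
    stop("fewer effective modes than requested components")
  }
  u <- eg$vectors[, seq_len(n_components), drop = FALSE]
  # modes in sqrt(w) space, rescaled to w-orthonormal maps
  m <- crossprod(b, u)
  m <- sweep(m, 2, sqrt(lambda * (n - 1)), `/`)
  modes <- sweep(m, 1, sw, `/`)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  structure(
    list(variable = variable, grid = grid, mean_map = mu, modes = modes,
         weights = w, explained = lambda / total, eigenvalues = lambda,
         total_variance = total, n_fields = n),
    class = "eof_basis"
  )
}

#' @export
print.eof_basis <- function(x, ...) {
  cat(sprintf("<eof_basis> %s: %d modes on %d cells, explained %s\n",
              if (nzchar(x$variable)) x$variable else "(unnamed)",
              ncol(x$modes), length(x$mean_map),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' Project fields onto an EOF basis
#'
#' @param basis An `eof_basis`.
#' @param x Field vector (one map) or matrix (nights x cells).
#' @return Score matrix (nights x n_components).
#' @export
eof_scores <- function(basis, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(basis$mean_map)) stop("field is not on the basis grid")
  wm <- basis$weights * basis$modes
  # project first, then remove the projected mean (avoids centering the
  # full nights x cells matrix)
  sc <- x %*% wm
  sc <- sc - rep(as.vector(basis$mean_map %*% wm), each = nrow(sc))
  colnames(sc) <- paste0("eof", seq_len(ncol(sc)))
  sc
}

#' Reconstruct fields from EOF scores
#'
#' @param basis An `eof_basis`.
#' @param scores Score vector or matrix (nights x n_components).
#' @return Matrix of reconstructed fields (nights x cells).
#' @export
eof_reconstruct <- function(basis, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != ncol(basis$modes)) {
    stop("score dimension does not match the basis")
  }
  out <- scores %*% t(basis$modes)
  sweep(out, 2, basis$mean_map, `+`)
}
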