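# Functional PCA of vertical profiles, implemented as weighted discretized
# PCA: eigendecomposition of the quadrature-weight-scaled covariance of
# mean-centered profiles. With 13 fixed, equally spaced bins no basis
# smoothing is needed and the decomposition is exactly oracle-checkable
# against a dense SVD.

#' Fit a functional PCA basis to vertical profiles
#'
#' Profiles are mean-centered and decomposed under the weighted inner product
#' `<f, g> = sum_i w_i f_i g_i` with trapezoidal quadrature weights on the
#' altitude grid. The leading components are rescaled to be orthonormal under
#' that inner product. Signs are fixed so that component 1 has positive
#' weighted mean loading (a higher score means higher overall intensity) and
#' component 2 has positive weighted covariance with altitude (a higher score
#' means a higher mean flight altitude).
#'
#' @param x Numeric matrix of profiles (rows) by altitude bins (columns).
#'   Rows containing missing bins are excluded from the fit.
#' @param n_components Number of components to retain (default 2).
#' @param altitudes Altitude grid matching the columns of `x`.
#' @param weights Quadrature weights; default trapezoid via
#'   [quadrature_weights()]. Uniform weights (all 1) reproduce ordinary PCA.
#' @param variable Optional variable name carried in the basis.
#' @return An object of class `fpca_basis` with elements `mean`, `components`
#'   (bins x n_components), `weights`, `explained` (fraction of weighted
#'   variance per retained component) and `total_variance`.
#' @export
fit_fpca <- function(x, n_components = 2, altitudes = mig_altitudes(),
                     weights = NULL, variable = "") {
  x <- as.matrix(x)
  if (ncol(x) != length(altitudes)) {
    stop("profile length does not match the altitude grid")
  }
  weights <- weights %||% quadrature_weights(ncol(x))
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  if (n <= n_components) {
    stop("need more complete profiles than components")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sw <- sqrt(weights)
  b <- sweep(xc, 2, sw, `*`)
  cv <- crossprod(b) / (n - 1)
  total <- sum(diag(cv))
  if (total < 1e-12) stop("profiles are constant; no variance to decompose")
  eg <- eigen(cv, symmetric = TRUE)
  comp <- sweep(eg$vectors[, seq_len(n_components), drop = FALSE], 1, sw, `/`)
  lambda <- pmax(eg$values[seq_len(n_components)], 0)

  # sign conventions: PC1 ~ intensity, PC2 ~ altitude
  alt_bar <- sum(weights * altitudes) / sum(weights)
  for (k in seq_len(n_components)) {
    crit <- if (k == 1) {
      sum(weights * comp[, k])
    } else if (k == 2) {
      sum(weights * comp[, k] * (altitudes - alt_bar))
    } else {
      comp[which.max(abs(comp[, k])), k]
    }
    if (crit < 0) comp[, k] <- -comp[, k]
  }
  structure(
    list(variable = variable, altitudes = altitudes, mean = mu,
         components = comp, weights = weights,
         explained = lambda / total, eigenvalues = lambda,
         total_variance = total, n_profiles = n),
    class = "fpca_basis"
  )
}

#' @export
print.fpca_basis <- function(x, ...) {
  cat(sprintf("<fpca_basis> %s: %d components on %d bins, explained %s\n",
              if (nzchar(x$variable)) x$variable else "(unnamed)",
              ncol(x$components), length(x$mean),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' Project profiles onto an FPCA basis
#'
#' Scores are weighted inner products of the mean-centered profile with each
#' component. Missing bins are imputed with the basis mean profile (their
#' centered value is 0), which is unbiased under missingness unrelated to the
#' profile shape; the number of imputed bins is reported as an attribute.
#'
#' @param basis An `fpca_basis`.
#' @param x Profile vector or matrix (rows = profiles).
#' @return Score matrix (rows x n_components) with attribute `n_imputed`.
#' @export
fpca_scores <- function(basis, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(basis$mean)) stop("profile is not on the basis grid")
  xc <- sweep(x, 2, basis$mean)
  n_imputed <- sum(is.na(xc))
  xc[is.na(xc)] <- 0
  sc <- xc %*% (basis$weights * basis$components)
  colnames(sc) <- paste0("pc", seq_len(ncol(sc)))
  attr(sc, "n_imputed") <- n_imputed
  sc
}

#' Reconstruct profiles from FPCA scores
#'
#' Returns `mean + sum_k score_k * component_k`, the rank-`k` approximation
#' of the profile; used to turn predicted principal-component anomalies back
#' into full vertical profiles.
#'
#' @param basis An `fpca_basis`.
#' @param scores Score vector or matrix (rows x n_components).
#' @return Matrix of reconstructed profiles (rows x bins).
#' @export
fpca_reconstruct <- function(basis, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != ncol(basis$components)) {
    stop("score dimension does not match the basis")
  }
  out <- scores %*% t(basis$components)
  sweep(out, 2, basis$mean, `+`)
}
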