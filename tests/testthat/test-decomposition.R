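# FPCA and EOF: oracle equivalence (dense SVD/eigendecomposition computed
# independently in the tests), orthonormality, sign conventions, projection
# and reconstruction round-trips.

make_planted_profiles <- function(n = 200, noise = 0, seed = 1) {
  set.seed(seed)
  alt <- mig_altitudes()
  w <- quadrature_weights(13)
  shapes <- cbind(1 + exp(-alt / 900), sin(alt / 1000))
  b <- sweep(shapes, 1, sqrt(w), `*`)
  phi <- sweep(qr.Q(qr(b)), 1, sqrt(w), `/`)
  a <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1))
  mu <- 0.5 + alt / 5000
  x <- outer(rep(1, n), mu) + a %*% t(phi)
  if (noise > 0) x <- x + matrix(rnorm(n * 13, 0, noise), n)
  list(x = x, phi = phi, a = a, mu = mu, w = w, alt = alt)
}

test_that("FPCA recovers a planted noiseless basis to oracle accuracy", {
  p <- make_planted_profiles()
  basis <- fit_fpca(p$x)
  # oracle: dense SVD of the sqrt(weight)-scaled centered matrix
  xc <- scale(p$x, center = TRUE, scale = FALSE)
  sv <- svd(sweep(xc, 2, sqrt(p$w), `*`))
  oracle_span <- sv$v[, 1:2]
  fitted_span <- sweep(basis$components, 1, sqrt(p$w), `*`)
  planted_span <- sweep(p$phi, 1, sqrt(p$w), `*`)
  expect_lt(principal_angle(fitted_span, oracle_span), 1e-6)
  expect_lt(principal_angle(fitted_span, planted_span), 1e-6)
})

test_that("FPCA components are weighted-orthonormal with valid explained fractions", {
  p <- make_planted_profiles(noise = 0.3, seed = 2)
  basis <- fit_fpca(p$x)
  g <- crossprod(basis$components, basis$weights * basis$components)
  expect_lt(max(abs(g - diag(2))), 1e-10)
  expect_true(all(diff(basis$explained) <= 1e-12))
  expect_lte(sum(basis$explained), 1 + 1e-12)
  # internal consistency: explained fraction = score variance / total
  sc <- fpca_scores(basis, p$x)
  expect_equal(as.vector(apply(sc, 2, var)) / basis$total_variance,
               as.vector(basis$explained), tolerance = 1e-10)
})

test_that("FPCA sign conventions give intensity-like and altitude-like components", {
  p <- make_planted_profiles(noise = 0.2, seed = 3)
  basis <- fit_fpca(p$x)
  sc <- fpca_scores(basis, p$x)
  expect_gt(cor(sc[, 1], rowMeans(p$x)), 0)
  alt_bar <- sum(basis$weights * p$alt) / sum(basis$weights)
  expect_gt(sum(basis$weights * basis$components[, 2] * (p$alt - alt_bar)), 0)
})

test_that("FPCA with uniform weights equals ordinary PCA", {
  p <- make_planted_profiles(noise = 0.5, seed = 4)
  basis <- fit_fpca(p$x, weights = rep(1, 13))
  pr <- prcomp(p$x, center = TRUE, scale. = FALSE)
  expect_lt(principal_angle(basis$components, pr$rotation[, 1:2]), 1e-6)
  expect_equal(abs(as.vector(fpca_scores(basis, p$x))),
               abs(as.vector(pr$x[, 1:2])), tolerance = 1e-8)
})

test_that("FPCA scores and reconstruction invert each other", {
  p <- make_planted_profiles(seed = 5)
  basis <- fit_fpca(p$x)
  expect_equal(as.vector(fpca_scores(basis, basis$mean)), c(0, 0),
               tolerance = 1e-10)
  prof <- basis$mean + 2 * basis$components[, 1]
  expect_equal(as.vector(fpca_scores(basis, prof)), c(2, 0),
               tolerance = 1e-10)
  s <- cbind(c(1.5, -2, 0), c(0.3, 1, -4))
  expect_equal(unname(fpca_scores(basis, fpca_reconstruct(basis, s))),
               unname(s), tolerance = 1e-10, ignore_attr = TRUE)
  # identity on profiles lying in span(mean, phi1, phi2)
  expect_equal(fpca_reconstruct(basis, fpca_scores(basis, p$x)), p$x,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-2 FPCA reconstruction attains the Eckart-Young optimum", {
  p <- make_planted_profiles(noise = 0.4, seed = 6)
  basis <- fit_fpca(p$x)
  recon <- fpca_reconstruct(basis, fpca_scores(basis, p$x))
  w_err <- function(a, b) sum(sweep((a - b)^2, 2, p$w, `*`))
  err_fit <- w_err(recon, p$x)
  # oracle optimum: truncated SVD in the sqrt-weight geometry
  xc <- scale(p$x, center = TRUE, scale = FALSE)
  sv <- svd(sweep(xc, 2, sqrt(p$w), `*`))
  err_opt <- sum(sv$d[-(1:2)]^2)
  expect_lte(err_fit, err_opt * (1 + 1e-10))
  expect_gte(err_fit, err_opt * (1 - 1e-10))
})

test_that("FPCA rejects degenerate inputs", {
  expect_error(fit_fpca(matrix(1, 10, 13)), "constant")
  expect_error(fit_fpca(matrix(rnorm(13), 1, 13)), "more complete profiles")
  p <- make_planted_profiles()
  expect_error(fpca_scores(fit_fpca(p$x), rep(0, 12)), "grid")
})

test_that("missing bins are mean-imputed for scoring and counted", {
  p <- make_planted_profiles(seed = 7)
  basis <- fit_fpca(p$x)
  prof <- p$x[1, ]
  prof[c(2, 9)] <- NA
  sc <- fpca_scores(basis, prof)
  expect_identical(attr(sc, "n_imputed"), 2L)
  expect_true(all(is.finite(sc)))
})

make_planted_fields <- function(n = 80, noise = 0, seed = 1) {
  set.seed(seed)
  grid <- make_grid(lon = seq(-20, 10, 2.5), lat = seq(10, 70, 2.5))
  w <- migcast:::grid_area_weights(grid)
  raw <- sapply(1:4, function(k) {
    exp(-((grid$cell_lon + 25 - 12 * k)^2 + (grid$cell_lat - 15 * k + 5)^2) /
          (2 * 64))
  })
  modes <- sweep(qr.Q(qr(sweep(raw, 1, sqrt(w), `*`))), 1, sqrt(w), `/`)
  a <- matrix(rnorm(n * 4), n) %*% diag(c(4, 3, 2, 1))
  mu <- 10 + grid$cell_lat / 10
  x <- outer(rep(1, n), mu) + a %*% t(modes)
  if (noise > 0) x <- x + matrix(rnorm(length(x), 0, noise), n)
  list(x = x, modes = modes, a = a, grid = grid, w = w)
}

test_that("EOF recovers planted noiseless modes to oracle accuracy", {
  p <- make_planted_fields()
  basis <- fit_eof(p$x, grid = p$grid)
  xc <- scale(p$x, center = TRUE, scale = FALSE)
  sv <- svd(sweep(xc, 2, sqrt(p$w), `*`))
  fitted <- sweep(basis$modes, 1, sqrt(p$w), `*`)
  planted <- sweep(p$modes, 1, sqrt(p$w), `*`)
  expect_lt(principal_angle(fitted, sv$v[, 1:4]), 1e-6)
  expect_lt(principal_angle(fitted, planted), 1e-6)
  # orthonormal modes, non-increasing explained fractions
  g <- crossprod(basis$modes, basis$weights * basis$modes)
  expect_lt(max(abs(g - diag(4))), 1e-10)
  expect_true(all(diff(basis$explained) <= 1e-12))
})

test_that("EOF scores are uncorrelated on the training nights", {
  p <- make_planted_fields(seed = 2)
  basis <- fit_eof(p$x, grid = p$grid)
  sc <- eof_scores(basis, p$x)
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("EOF reconstruction is the identity on the mode span", {
  p <- make_planted_fields(seed = 3)
  basis <- fit_eof(p$x, grid = p$grid)
  f <- p$x[5, ]
  expect_equal(as.vector(eof_reconstruct(basis, eof_scores(basis, f))), f,
               tolerance = 1e-8)
})

test_that("EOF rejects constant fields and undersized inputs", {
  grid <- make_grid(lon = seq(0, 5, 1), lat = seq(40, 45, 1))
  x <- matrix(3, 10, grid$n_cells)
  expect_error(fit_eof(x, grid = grid), "constant")
  expect_error(fit_eof(x[1:3, ], grid = grid), "fewer nights")
  expect_error(fit_eof(matrix(rnorm(50), 10, 5), grid = grid), "grid")
})
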