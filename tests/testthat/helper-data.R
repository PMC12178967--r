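# Shared fixtures (memoized so that expensive synthetic datasets are built
# once per test run) and small numerical helpers.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tiny_config <- function(...) {
  args <- list(n_years = 2, radars = default_radars(3), months_spring = 3,
               months_autumn = 10, seed = 101)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

tiny_dataset <- function() fixture("tiny", generate_dataset(tiny_config()))

tiny_panel <- function() fixture("tiny_panel", {
  filter_insects(build_nightly_profiles(tiny_dataset()$raw))
})

tiny_pipeline <- function() fixture("tiny_pipeline", {
  ds <- tiny_dataset()
  fit_pipeline(tiny_panel(), ds$local, ds$synoptic, ds$radars)
})

tiny_features <- function() fixture("tiny_ft", {
  ds <- tiny_dataset()
  assemble_features(tiny_pipeline(), tiny_panel(), ds$local, ds$synoptic)
})

# largest principal angle between the column spans of two matrices
principal_angle <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb))$d
  acos(max(-1, min(1, min(s))))
}

# simple linear synthetic feature table for model unit tests
linear_feature_table <- function(n, beta = 1, noise_sd = 0.3, seed = 1,
                                 n_years = 4) {
  set.seed(seed)
  p <- 10
  x <- matrix(rnorm(n * p), n)
  colnames(x) <- paste0("x", seq_len(p))
  ft <- as.data.frame(x)
  ft$z1 <- beta * x[, 1] + rnorm(n, 0, noise_sd)
  ft$year <- rep_len(seq_len(n_years), n)
  ft
}
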