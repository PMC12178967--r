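# Plain-text persistence of fitted components: FPCA/EOF bases (JSON metadata
# plus CSV arrays) and gradient-boosted model bundles (the booster's own JSON
# serialization plus a metadata sidecar).

#' Write and read FPCA bases
#'
#' A basis directory holds `meta.json` (variable name, altitudes, weights,
#' explained fractions) and `arrays.csv` (mean profile and component
#' loadings, one row per altitude bin).
#'
#' @param basis An `fpca_basis` from [fit_fpca()].
#' @param dir Directory to write (created if needed).
#' @return `read_fpca_basis` returns the restored `fpca_basis`.
#' @export
write_fpca_basis <- function(basis, dir) {
  stopifnot(inherits(basis, "fpca_basis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- basis[c("variable", "altitudes", "weights", "explained",
                  "eigenvalues", "total_variance", "n_profiles")]
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  arr <- data.frame(mean = basis$mean)
  for (k in seq_len(ncol(basis$components))) {
    arr[[paste0("component", k)]] <- basis$components[, k]
  }
  data.table::fwrite(arr, file.path(dir, "arrays.csv"))
  invisible(dir)
}

#' @rdname write_fpca_basis
#' @export
read_fpca_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  arr <- data.table::fread(file.path(dir, "arrays.csv"))
  comp <- as.matrix(arr[, -1])
  dimnames(comp) <- NULL
  structure(
    list(variable = meta$variable, altitudes = meta$altitudes,
         mean = arr$mean, components = comp, weights = meta$weights,
         explained = meta$explained, eigenvalues = meta$eigenvalues,
         total_variance = meta$total_variance,
         n_profiles = meta$n_profiles),
    class = "fpca_basis"
  )
}

#' Write and read EOF bases
#'
#' A basis directory holds `meta.json` (variable, grid lines, explained
#' fractions) and `arrays.csv` (mean map and mode loadings, one row per
#' grid cell).
#'
#' @param basis An `eof_basis` from [fit_eof()].
#' @param dir Directory to write.
#' @return `read_eof_basis` returns the restored `eof_basis`.
#' @export
write_eof_basis <- function(basis, dir) {
  stopifnot(inherits(basis, "eof_basis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(variable = basis$variable, lon = basis$grid$lon,
               lat = basis$grid$lat, explained = basis$explained,
               eigenvalues = basis$eigenvalues,
               total_variance = basis$total_variance,
               n_fields = basis$n_fields)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  arr <- data.frame(mean_map = basis$mean_map)
  for (k in seq_len(ncol(basis$modes))) {
    arr[[paste0("mode", k)]] <- basis$modes[, k]
  }
  data.table::fwrite(arr, file.path(dir, "arrays.csv"))
  invisible(dir)
}

#' @rdname write_eof_basis
#' @export
read_eof_basis <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  arr <- data.table::fread(file.path(dir, "arrays.csv"))
  modes <- as.matrix(arr[, -1])
  dimnames(modes) <- NULL
  grid <- make_grid(lon = meta$lon, lat = meta$lat)
  structure(
    list(variable = meta$variable, grid = grid, mean_map = arr$mean_map,
         modes = modes, weights = grid_area_weights(grid),
         explained = meta$explained, eigenvalues = meta$eigenvalues,
         total_variance = meta$total_variance, n_fields = meta$n_fields),
    class = "eof_basis"
  )
}

#' Write and read gradient-boosted model bundles
#'
#' A bundle directory holds `ensemble.json` (the booster serialized by its
#' own library) and `meta.json` (target, predictor columns, parameters).
#'
#' @param model A `gbt_model` from [train_gbt()].
#' @param dir Directory to write.
#' @return `read_gbt` returns the restored `gbt_model`; its predictions are
#'   identical to the original's.
#' @export
write_gbt <- function(model, dir) {
  stopifnot(inherits(model, "gbt_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "ensemble.json"))
  jsonlite::write_json(
    list(target = model$target, columns = model$columns,
         params = model$params),
    file.path(dir, "meta.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_gbt
#' @export
read_gbt <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "ensemble.json"))
  structure(
    list(booster = booster, columns = meta$columns, target = meta$target,
         params = as.list(meta$params)),
    class = "gbt_model"
  )
}
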