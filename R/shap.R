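# Shapley attribution of the tree ensembles, group aggregation, and
# reconstruction of favorable/unfavorable weather patterns.

# Extract the forest of a gbt_model as plain vectors (from the model's JSON
# serialization, which stores split thresholds and leaf values exactly).
.xgb_forest <- function(model) {
  stopifnot(inherits(model, "gbt_model"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  xgboost::xgb.save(model$booster, tmp)
  js <- jsonlite::fromJSON(tmp, simplifyVector = FALSE)
  base_score <- as.numeric(js$learner$learner_model_param$base_score)
  trees <- lapply(js$learner$gradient_booster$model$trees, function(tr) {
    list(
      left = as.integer(unlist(tr$left_children)),
      right = as.integer(unlist(tr$right_children)),
      split_index = as.integer(unlist(tr$split_indices)),
      default_left = as.integer(unlist(tr$default_left)),
      threshold = as.numeric(unlist(tr$split_conditions)),
      value = as.numeric(unlist(tr$split_conditions)),
      cover = as.numeric(unlist(tr$sum_hessian))
    )
  })
  list(trees = trees, base_score = base_score)
}

#' Exact SHAP attributions for a gradient-boosted model
#'
#' Computes exact tree-Shapley attributions (TreeSHAP) for every row, in
#' double precision: the bias (the ensemble's cover-weighted expected value)
#' plus the per-feature attributions reproduce the model prediction to
#' machine precision.
#'
#' @param model A `gbt_model` from [train_gbt()].
#' @param ft Feature table (or matrix) with the model's predictor columns.
#' @return Object of class `mig_shap`: list with `values` (rows x features),
#'   `bias` (scalar expected value), and `pred` (`bias + rowSums(values)`,
#'   the double-precision model prediction).
#' @export
compute_shap <- function(model, ft) {
  x <- if (is.matrix(ft)) {
    if (!all(model$columns %in% colnames(x <- ft))) {
      stop("matrix lacks the model's feature columns")
    }
    x[, model$columns, drop = FALSE]
  } else {
    if (!all(model$columns %in% names(ft))) {
      stop("feature table lacks the model's feature columns")
    }
    .feature_matrix(ft, model$columns)
  }
  forest <- .xgb_forest(model)
  contrib <- treeshap_cpp(forest$trees, x, forest$base_score)
  values <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(values) <- model$columns
  bias <- contrib[1, ncol(contrib)]
  structure(
    list(values = values, bias = bias, pred = bias + rowSums(values),
         target = model$target),
    class = "mig_shap"
  )
}

#' @export
print.mig_shap <- function(x, ...) {
  top <- sort(colMeans(abs(x$values)), decreasing = TRUE)[1:5]
  cat(sprintf("<mig_shap> %d rows x %d features; top mean |SHAP|:\n",
              nrow(x$values), ncol(x$values)))
  for (i in seq_along(top)) {
    cat(sprintf("  %-18s %.4f\n", names(top)[i], top[i]))
  }
  invisible(x)
}

# double-precision forest prediction (same routing as SHAP); used for
# consistency checks against the training library's float predictions
forest_predict <- function(model, ft) {
  x <- .feature_matrix(ft, model$columns)
  forest <- .xgb_forest(model)
  forest_predict_cpp(forest$trees, x, forest$base_score)
}

#' Aggregate SHAP values over feature groups
#'
#' Sums per-feature attributions within disjoint feature groups; features
#' not covered by any group are collected in `(other)` so that the group
#' values still partition the full attribution (their sum plus the bias
#' equals the prediction row by row). Overlapping groups or unknown feature
#' names are an error.
#'
#' @param shap A `mig_shap` from [compute_shap()].
#' @param groups Named list of character vectors of feature names, e.g.
#'   [metric_groups()] or [scale_groups()].
#' @return Object of class `shap_groups`: `per_row` matrix (rows x groups),
#'   `mean_abs` (mean absolute group contribution), `groups`.
#' @export
aggregate_shap_groups <- function(shap, groups) {
  stopifnot(inherits(shap, "mig_shap"))
  feats <- colnames(shap$values)
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("groups overlap: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  unknown <- setdiff(all_members, feats)
  if (length(unknown) > 0) {
    stop("unknown features in grouping: ", paste(unknown, collapse = ", "))
  }
  rest <- setdiff(feats, all_members)
  if (length(rest) > 0) groups <- c(groups, list(`(other)` = rest))
  per_row <- sapply(groups, function(g) {
    rowSums(shap$values[, g, drop = FALSE])
  })
  if (is.null(dim(per_row))) per_row <- matrix(per_row, nrow = 1,
                                               dimnames = list(NULL, names(groups)))
  structure(
    list(per_row = per_row, mean_abs = colMeans(abs(per_row)),
         groups = groups, bias = shap$bias, pred = shap$pred),
    class = "shap_groups"
  )
}

#' @export
print.shap_groups <- function(x, ...) {
  cat("<shap_groups> mean |group SHAP|:\n")
  v <- sort(x$mean_abs, decreasing = TRUE)
  for (i in seq_along(v)) cat(sprintf("  %-28s %.4f\n", names(v)[i], v[i]))
  invisible(x)
}

# parse a basis feature name into (kind, var, pc, slice)
.parse_feature <- function(name) {
  m <- regmatches(name, regexec("^([a-z0-9]+)_(pc|eof)([0-9]+)_(now|lag[1-3])$",
                                name))[[1]]
  if (length(m) == 0) return(NULL)
  list(var = m[2], kind = m[3], pc = as.integer(m[4]), slice = m[5])
}

#' Reconstruct favorable and unfavorable weather patterns
#'
#' For every PC-type predictor, averages its value over the rows where its
#' SHAP attribution is positive (favorable conditions) or negative
#' (unfavorable), then maps the averaged PC vectors back through the fitted
#' bases: local profile anomalies are added to the basis mean profile per
#' variable and time slice (now, -1, -2, -3 nights), synoptic EOF scores are
#' expanded to anomaly maps. Features with no positive (or negative) SHAP
#' rows are reported as `NA` rather than an error.
#'
#' @param shap A `mig_shap`.
#' @param ft Feature table aligned with the SHAP rows.
#' @param pipeline Fitted [fit_pipeline()] providing the bases.
#' @return Object of class `favorable_patterns`: `profiles[[var]][[cond]]` is
#'   a 13 x 4 matrix (altitudes x slices), `maps[[var]][[cond]]` a cells x 4
#'   matrix, plus `feature_means` (per-feature overall / favorable /
#'   unfavorable means and row counts) and `scalars` for cloud/precip.
#' @export
reconstruct_favorable_patterns <- function(shap, ft, pipeline) {
  stopifnot(inherits(shap, "mig_shap"))
  feats <- colnames(shap$values)
  stopifnot(nrow(shap$values) == nrow(ft))

  fm <- lapply(feats, function(f) {
    v <- ft[[f]]
    s <- shap$values[, f]
    pos <- which(s > 0 & !is.na(v))
    neg <- which(s < 0 & !is.na(v))
    data.frame(feature = f,
               overall = mean(v, na.rm = TRUE),
               favorable = if (length(pos)) mean(v[pos]) else NA_real_,
               unfavorable = if (length(neg)) mean(v[neg]) else NA_real_,
               n_pos = length(pos), n_neg = length(neg))
  })
  fm <- do.call(rbind, fm)

  conds <- c("overall", "favorable", "unfavorable")
  slices <- FEATURE_SLICES
  get_mean <- function(f, cond) fm[[cond]][fm$feature == f]

  profiles <- list()
  for (v in LOCAL_VARS) {
    basis <- pipeline$local_bases[[v]]
    profiles[[v]] <- lapply(stats::setNames(conds, conds), function(cond) {
      out <- matrix(NA_real_, length(basis$mean), length(slices),
                    dimnames = list(NULL, slices))
      for (j in seq_along(slices)) {
        a <- sapply(seq_len(pipeline$n_fpca), function(k) {
          get_mean(sprintf("%s_pc%d_%s", v, k, slices[j]), cond)
        })
        if (!any(is.na(a))) {
          out[, j] <- as.vector(fpca_reconstruct(basis, a))
        }
      }
      out
    })
  }

  maps <- list()
  for (v in SYNOPTIC_VARS) {
    basis <- pipeline$eof_bases[[v]]
    maps[[v]] <- lapply(stats::setNames(conds, conds), function(cond) {
      out <- matrix(NA_real_, length(basis$mean_map), length(slices),
                    dimnames = list(NULL, slices))
      for (j in seq_along(slices)) {
        a <- sapply(seq_len(pipeline$n_eof), function(k) {
          get_mean(sprintf("%s_eof%d_%s", v, k, slices[j]), cond)
        })
        if (!any(is.na(a))) {
          out[, j] <- as.vector(eof_reconstruct(basis, a))
        }
      }
      out
    })
  }

  scalars <- fm[grepl("^(cloud|precip)_", fm$feature), ]
  structure(
    list(profiles = profiles, maps = maps, scalars = scalars,
         feature_means = fm, altitudes = pipeline$bird_basis$altitudes,
         grid = pipeline$eof_bases[[1]]$grid),
    class = "favorable_patterns"
  )
}

#' @export
print.favorable_patterns <- function(x, ...) {
  cat(sprintf(
    "<favorable_patterns> %d local variables, %d synoptic variables, 4 time slices\n",
    length(x$profiles), length(x$maps)))
  invisible(x)
}
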