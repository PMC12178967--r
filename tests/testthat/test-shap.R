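# Exact tree-Shapley attribution: additivity, agreement with the training
# library's own (float-precision) attribution, group aggregation, and
# favorable-pattern reconstruction.

shap_toy_model <- function(n = 2000, p = 8, seed = 21, nrounds = 60,
                           with_na = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n)
  colnames(x) <- paste0("f", seq_len(p))
  if (with_na) x[sample(n * p, n)] <- NA
  m23 <- rowMeans(x[, 2:3], na.rm = TRUE)
  m23[is.nan(m23)] <- 0
  y <- 0.9 * ifelse(is.na(x[, 1]), 0.4, x[, 1]) + 0.4 * m23 +
    rnorm(n, 0, 0.3)
  ft <- as.data.frame(x)
  ft$z1 <- y
  mod <- train_gbt(ft, "z1", gbt_params(nrounds = nrounds),
                   columns = colnames(x))
  list(model = mod, ft = ft, x = x)
}

test_that("a single stump attributes everything to its split feature", {
  set.seed(22)
  ft <- data.frame(f1 = rnorm(500), f2 = rnorm(500))
  ft$z1 <- ifelse(ft$f1 > 0, 1, -1)
  mod <- train_gbt(ft, "z1", gbt_params(nrounds = 1, max_leaves = 2,
                                        eta = 1, min_child_weight = 1),
                   columns = c("f1", "f2"))
  sh <- compute_shap(mod, ft)
  expect_equal(unname(sh$values[, "f2"]), rep(0, 500))
  expect_equal(sh$values[, "f1"], sh$pred - sh$bias, tolerance = 1e-12)
})

test_that("attributions are additive to machine precision in double arithmetic", {
  toy <- shap_toy_model(with_na = TRUE)
  sh <- compute_shap(toy$model, toy$ft)
  pred_dbl <- migcast:::forest_predict(toy$model, toy$ft)
  expect_lt(max(abs(sh$bias + rowSums(sh$values) - pred_dbl)), 1e-10)
  # the double-precision traversal agrees with the library's float32
  # prediction path to float tolerance
  expect_lt(max(abs(pred_dbl - predict(toy$model, toy$ft))), 1e-5)
})

test_that("attributions match the training library's own TreeSHAP", {
  toy <- shap_toy_model(with_na = TRUE, seed = 23)
  sh <- compute_shap(toy$model, toy$ft)
  ct <- stats::predict(toy$model$booster,
                       xgboost::xgb.DMatrix(toy$x, missing = NA, nthread = 1),
                       predcontrib = TRUE)
  expect_lt(max(abs(sh$values - ct[, seq_len(ncol(toy$x))])), 1e-4)
  expect_lt(abs(sh$bias - ct[1, ncol(ct)]), 1e-6)
})

test_that("features absent from every tree get zero attribution", {
  set.seed(24)
  ft <- data.frame(f1 = rnorm(800), f2 = rnorm(800), dead = 0)
  ft$z1 <- ft$f1 + 0.5 * ft$f2 + rnorm(800, 0, 0.2)
  # a constant column can never host a split, so it must get zero credit
  mod <- train_gbt(ft, "z1", gbt_params(nrounds = 40),
                   columns = c("f1", "f2", "dead"))
  sh <- compute_shap(mod, ft)
  expect_equal(unname(sh$values[, "dead"]), rep(0, 800))
  expect_gt(mean(abs(sh$values[, "f1"])), 0)
})

test_that("group aggregation preserves additivity and rejects bad groupings", {
  toy <- shap_toy_model(seed = 25)
  sh <- compute_shap(toy$model, toy$ft)
  groups <- list(a = c("f1", "f2"), b = c("f3", "f4", "f5"))
  ag <- aggregate_shap_groups(sh, groups)
  expect_identical(colnames(ag$per_row), c("a", "b", "(other)"))
  expect_lt(max(abs(rowSums(ag$per_row) + ag$bias - sh$pred)), 1e-10)
  # singleton groups reproduce the per-feature table
  singles <- as.list(stats::setNames(colnames(sh$values),
                                     colnames(sh$values)))
  ag1 <- aggregate_shap_groups(sh, singles)
  expect_equal(ag1$per_row[, colnames(sh$values)], sh$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(aggregate_shap_groups(sh, list(a = "f1", b = c("f1", "f2"))),
               "overlap")
  expect_error(aggregate_shap_groups(sh, list(a = "nope")), "unknown")
})

test_that("the two canonical groupings give identical row totals", {
  ds <- tiny_dataset()
  ft <- tiny_features()
  sp <- ft[ft$season == "spring", ]
  mod <- train_gbt(sp[sp$year == min(sp$year), ], "z1",
                   gbt_params(nrounds = 40))
  sh <- compute_shap(mod, sp)
  t1 <- rowSums(aggregate_shap_groups(sh, metric_groups())$per_row)
  t2 <- rowSums(aggregate_shap_groups(sh, scale_groups())$per_row)
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("noise features attract less attribution than planted-effect features", {
  toy <- shap_toy_model(seed = 26, n = 3000)
  sh <- compute_shap(toy$model, toy$ft)
  ma <- colMeans(abs(sh$values))
  expect_gt(ma["f1"], max(ma[paste0("f", 4:8)]))
})

test_that("favorable and unfavorable averages bracket the overall mean for a monotone model", {
  set.seed(27)
  n <- 1500
  ft <- data.frame(matrix(rnorm(n * 3), n))
  names(ft) <- c("u_pc1_now", "u_pc2_now", "v_pc1_now")
  ft$z1 <- ft$u_pc1_now  # strictly monotone single-feature response
  mod <- train_gbt(ft, "z1", gbt_params(nrounds = 60),
                   columns = names(ft)[1:3])
  sh <- compute_shap(mod, ft)
  v <- ft$u_pc1_now
  s <- sh$values[, "u_pc1_now"]
  expect_gt(mean(v[s > 0]), mean(v))
  expect_lt(mean(v[s < 0]), mean(v))
})

test_that("an all-zero attribution yields undefined favorable patterns", {
  ds <- tiny_dataset()
  pl <- tiny_pipeline()
  ft <- tiny_features()
  sh <- structure(
    list(values = matrix(0, nrow(ft), 117,
                         dimnames = list(NULL, feature_columns(ft))),
         bias = 0.2, pred = rep(0.2, nrow(ft)), target = "z1"),
    class = "mig_shap"
  )
  fp <- reconstruct_favorable_patterns(sh, ft, pl)
  expect_true(all(is.na(fp$profiles$u$favorable)))
  expect_true(all(is.na(fp$maps$msl$unfavorable)))
  # the unconditional average is still defined
  expect_true(all(is.finite(fp$profiles$u$overall)))
})
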