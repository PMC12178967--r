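# Gradient-boosted anomaly models, benchmarks, tuning, and the
# leave-one-year-out cross-validation loop.

test_that("a deep enough ensemble memorizes a copied feature", {
  ft <- linear_feature_table(400, noise_sd = 0)
  mod <- train_gbt(ft, "z1", gbt_params(nrounds = 300, max_leaves = 31,
                                        eta = 0.3, min_child_weight = 1),
                   columns = paste0("x", 1:10))
  pred <- predict(mod, ft)
  expect_gt(1 - var(ft$z1 - pred) / var(ft$z1), 0.99)
})

test_that("pure-noise targets give near-zero held-out skill", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    ft <- linear_feature_table(200, beta = 0, noise_sd = 1, seed = seed)
    tr <- seq_len(150)
    mod <- train_gbt(ft[tr, ], "z1", gbt_params(nrounds = 60),
                     columns = paste0("x", 1:10))
    pred <- predict(mod, ft[-tr, ])
    obs <- ft$z1[-tr]
    r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    if (r2 <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a planted linear effect is learned with the expected skill", {
  # beta = 1, noise sd 0.3: explainable R^2 = 1/(1 + 0.09) ~ 0.92
  ft <- linear_feature_table(2000, beta = 1, noise_sd = 0.3, seed = 11)
  tr <- seq_len(1500)
  mod <- train_gbt(ft[tr, ], "z1", gbt_params(nrounds = 200),
                   columns = paste0("x", 1:10))
  pred <- predict(mod, ft[-tr, ])
  obs <- ft$z1[-tr]
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_gte(r2, 0.5)
})

test_that("training is deterministic and zero-variance targets are rejected", {
  ft <- linear_feature_table(300, seed = 12)
  m1 <- train_gbt(ft, "z1", columns = paste0("x", 1:10))
  m2 <- train_gbt(ft, "z1", columns = paste0("x", 1:10))
  expect_identical(predict(m1, ft), predict(m2, ft))
  ft$z1 <- 1
  expect_error(train_gbt(ft, "z1", columns = paste0("x", 1:10)),
               "degenerate")
})

test_that("random-search tuning logs a running maximum and respects the budget", {
  ft <- linear_feature_table(300, seed = 13)
  obj <- function(p) -((p$eta - 0.1)^2) - p$lambda / 100
  res1 <- tune_gbt(ft, budget = 1, seed = 5, objective = obj)
  expect_identical(nrow(res1$log), 1L)
  res <- tune_gbt(ft, budget = 12, seed = 5, objective = obj)
  expect_identical(nrow(res$log), 12L)
  expect_true(all(diff(res$log$best_so_far) >= 0))
  expect_identical(res$best_score, max(res$log$score))
  # deterministic draws given the seed
  res2 <- tune_gbt(ft, budget = 12, seed = 5, objective = obj)
  expect_identical(res$log, res2$log)
})

test_that("tuned parameters are at least as good as the draws they beat", {
  ft <- linear_feature_table(600, beta = 1, noise_sd = 0.5, seed = 14)
  res <- tune_gbt(ft, budget = 4, seed = 2, columns = paste0("x", 1:10))
  expect_true(all(res$best_score >= res$log$score))
  expect_true(res$best_params$nrounds %in% 50:500)
})

test_that("the local-only column set has the documented 17 members", {
  cols <- local_only_columns()
  expect_identical(length(cols), 17L)
  expect_true(all(grepl("_now$", setdiff(cols, c("lon", "lat", "antenna",
                                                 "solar_decl", "time_angle")))))
  expect_false(any(grepl("eof|lag", cols)))
})

test_that("profile prediction destandardizes and reconstructs; z = 0 is phenology", {
  ds <- tiny_dataset()
  pl <- tiny_pipeline()
  ft <- tiny_features()
  pred0 <- predict_profiles(pl, ft, matrix(0, nrow(ft), 2))
  expect_identical(dim(pred0), c(nrow(ft), 13L))
  expect_true(all(is.finite(pred0)))
  expect_equal(pred0, benchmark_phenology(pl, ft))
  # feeding the true targets reproduces the rank-2 truncation of the profile
  panel <- tiny_panel()
  key <- paste(panel$meta$radar, panel$meta$night, panel$meta$slot)
  pi <- match(paste(ft$radar, ft$night, ft$slot), key)
  pred_true <- predict_profiles(pl, ft, cbind(ft$z1, ft$z2))
  vals <- panel$values[pi, ]
  vals[!panel$valid[pi, ]] <- NA
  sc <- fpca_scores(pl$bird_basis, vals)
  trunc2 <- fpca_reconstruct(pl$bird_basis, sc)
  expect_equal(pred_true, trunc2, tolerance = 1e-8)
})

test_that("the per-altitude benchmark expands rows by 13 and uses only local columns", {
  ds <- tiny_dataset()
  ft <- tiny_features()
  panel <- tiny_panel()
  tab <- migcast:::.per_altitude_table(ft[1:50, ], panel, ds$local,
                                       panel$altitudes)
  expect_identical(nrow(tab), 50L * 13L)
  ba <- benchmark_per_altitude(ft[ft$year == min(ft$year), ],
                               ft[ft$year == max(ft$year), ][1:40, ],
                               panel, ds$local,
                               params = gbt_params(nrounds = 20))
  expect_identical(dim(ba$pred), c(40L, 13L))
  expect_false(any(grepl("eof|lag|_pc", ba$model$columns)))
})

test_that("leave-one-year-out cross-validation produces one fold per year, reproducibly", {
  ds <- tiny_dataset()
  panel <- tiny_panel()
  run <- function() {
    cross_validate_years(panel, ds$local, ds$synoptic, ds$radars,
                         models = c("full", "phenology"),
                         params = gbt_params(nrounds = 30),
                         seasons = "spring", keep_fold_models = FALSE)
  }
  cv <- run()
  expect_identical(length(cv$folds), 2L)
  expect_identical(nrow(cv$results), 2L * 2L)  # 2 models x 2 years
  expect_true(all(cv$results$r2 <= 1))
  cv2 <- run()
  expect_identical(cv$results, cv2$results)
  # held-out self-thresholding is a documented alternative convention
  cv3 <- cross_validate_years(panel, ds$local, ds$synoptic, ds$radars,
                              models = "phenology",
                              seasons = "spring",
                              peak_threshold_source = "heldout",
                              keep_fold_models = FALSE)
  expect_true(all(cv3$results$f1 >= 0 & cv3$results$f1 <= 1))
})

test_that("models beat phenology when weather effects are planted", {
  ds <- tiny_dataset()  # planted (0.8, 0.5, 0.5) effects
  panel <- tiny_panel()
  cv <- cross_validate_years(panel, ds$local, ds$synoptic, ds$radars,
                             models = c("full", "phenology"),
                             params = gbt_params(nrounds = 60),
                             seasons = c("spring", "autumn"),
                             keep_fold_models = FALSE)
  r2 <- cv_mean_r2(cv)
  expect_gt(r2[["full"]], r2[["phenology"]])
})
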