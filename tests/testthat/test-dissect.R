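fit_gbr <- function(X, y, nrounds = 100, depth = 3, seed = 1) {
  fit_model(model_spec("GBR", grid = list(list(nrounds = nrounds,
                                               max_depth = depth,
                                               eta = 0.1)), seed = seed),
            X, y)
}

test_that("impurity importance is normalized and ranks the informative feature", {
  set.seed(7)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- sin(X[, 1]) * 2 + rnorm(200, 0, 0.1)
  fit <- fit_gbr(X, y)
  imp <- mdi_ranking(fit)
  expect_equal(sum(imp$mdi), 1, tolerance = 1e-9)
  expect_true(all(imp$mdi >= 0))
  expect_equal(imp$feature[1], "x1")

  # for ranger too
  rf <- fit_model(model_spec("RF", grid = list(list(num_trees = 100,
                                                    mtry_frac = 0.5))), X, y)
  expect_equal(mdi_ranking(rf)$feature[1], "x1")

  svr <- fit_model(model_spec("SVR", grid = list(list(cost = 1,
                                                      gamma_mult = 1))), X, y)
  expect_error(mdi_ranking(svr), "tree")
})

test_that("TreeSHAP attributions satisfy local accuracy on every sample", {
  set.seed(8)
  X <- matrix(rnorm(150 * 6), 150, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 1] * X[, 2] + X[, 3] + rnorm(150, 0, 0.2)
  fit <- fit_gbr(X, y, nrounds = 300, depth = 6)
  sh <- shapley_attributions(fit, X)
  expect_lt(max(abs(sh$base_value + rowSums(sh$values) - sh$prediction)),
            1e-6)
  # the double-precision evaluation tracks the library's float predictions
  expect_lt(max(abs(sh$prediction - predict(fit, X))), 1e-4)
  # agrees with the boosting library's own (single-precision) attribution
  booster <- fit$fits[[1]]
  ref <- predict(booster, X, predcontrib = TRUE)
  expect_lt(max(abs(sh$values - ref[, 1:6])), 1e-4)
})

test_that("depth-1 attributions match exhaustive Shapley enumeration", {
  set.seed(9)
  p <- 5
  X <- matrix(rnorm(40 * p), 40, p)
  forest <- hand_forest(list(
    list(feature = 1, threshold = 0.2, left_value = -1.3, right_value = 2.1,
         left_cover = 25, right_cover = 15),
    list(feature = 3, threshold = -0.5, left_value = 0.7, right_value = -0.4,
         left_cover = 12, right_cover = 28),
    list(feature = 1, threshold = -0.1, left_value = 0.5, right_value = -0.2,
         left_cover = 18, right_cover = 22)))
  res <- forest_shap(forest, X, base_score = 0.3)
  # local accuracy against the double-precision forest evaluation
  pred <- forest_predict(forest, X, base_score = 0.3)
  expect_equal(res$base_value + rowSums(res$phi), pred, tolerance = 1e-12)
  # exhaustive oracle over all 2^p feature subsets: for depth-1 trees the
  # cover shares define the conditioning distribution, so a background
  # realizing those shares exactly makes the enumeration deterministic
  two_tree <- hand_forest(list(
    list(feature = 1, threshold = 0.2, left_value = -1.3, right_value = 2.1,
         left_cover = 25, right_cover = 15),
    list(feature = 3, threshold = -0.5, left_value = 0.7, right_value = -0.4,
         left_cover = 12, right_cover = 28)))
  bg <- matrix(0, 40, p)
  bg[, 1] <- c(rep(0.2 - 1, 25), rep(0.2 + 1, 15))    # 25/15 cover split
  bg[, 3] <- c(rep(-0.5 - 1, 12), rep(-0.5 + 1, 28))  # 12/28 cover split
  res2 <- forest_shap(two_tree, X[1:5, , drop = FALSE], base_score = 0)
  for (i in 1:5) {
    phi_bf <- brute_force_shap(two_tree, X[i, ], bg, base_score = 0)
    expect_equal(unname(res2$phi[i, ]), phi_bf, tolerance = 1e-10)
  }
  # dummy features (never split on) attribute exactly zero
  expect_equal(max(abs(res2$phi[, c(2, 4, 5)])), 0)
})

test_that("symmetric trees attribute duplicated structure equally", {
  # two trees, identical splits on two different features
  forest <- hand_forest(list(
    list(feature = 1, threshold = 0, left_value = -1, right_value = 1,
         left_cover = 20, right_cover = 20),
    list(feature = 2, threshold = 0, left_value = -1, right_value = 1,
         left_cover = 20, right_cover = 20)))
  X <- cbind(c(1, -1, 0.5), c(1, -1, 0.5))
  res <- forest_shap(forest, X)
  expect_equal(res$phi[, 1], res$phi[, 2], tolerance = 1e-12)
})

test_that("partial dependence reflects additive structure", {
  set.seed(11)
  X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * X[, 1]
  lr <- fit_model(model_spec("LR", interactions = FALSE), X, y)
  pd <- partial_dependence(lr, X, "a", grid = 11)
  slope <- diff(range(pd$pd)) / diff(range(pd$a))
  expect_equal(slope, 3, tolerance = 1e-6)

  # feature the model ignores: flat curve
  pd_b <- partial_dependence(lr, X, "b", grid = 11)
  expect_lt(diff(range(pd_b$pd)), 1e-9)

  # additive two-feature model: surface equals sum of 1-D curves + const
  y2 <- 2 * X[, 1] - X[, 2]
  lr2 <- fit_model(model_spec("LR", interactions = FALSE), X, y2)
  surf <- partial_dependence(lr2, X, c("a", "b"), grid = 5)
  pa <- partial_dependence(lr2, X, "a", grid = 5)
  pb <- partial_dependence(lr2, X, "b", grid = 5)
  recon <- outer(pa$pd, pb$pd, "+")
  expect_equal(surf$pd - mean(surf$pd),
               as.numeric(recon) - mean(recon), tolerance = 1e-8)

  Xc <- X; Xc[, "c"] <- 1
  expect_warning(pd_c <- partial_dependence(lr, Xc, "c", grid = 5),
                 "constant")
  expect_equal(nrow(pd_c), 1)
})

test_that("flat-attribution features have flat partial dependence", {
  set.seed(12)
  X <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1]  # noiseless: depth-1 boosting never needs the other features
  fit <- fit_model(model_spec("GBR", grid = list(list(nrounds = 20,
                                                      max_depth = 1,
                                                      eta = 0.3))), X, y)
  sh <- shapley_attributions(fit, X)
  zero_feats <- colnames(sh$values)[apply(abs(sh$values), 2, max) == 0]
  expect_setequal(zero_feats, c("x2", "x3", "x4"))
  for (f in zero_feats) {
    pd <- partial_dependence(fit, X, f, grid = 9)
    expect_lt(diff(range(pd$pd)), 1e-9)
  }
})

test_that("importance-correlation overlap mirrors the model-vs-statistics gap", {
  set.seed(13)
  X <- matrix(rnorm(300 * 6), 300, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 3 * X[, 1] * X[, 2] + 0.5 * X[, 4] + rnorm(300, 0, 0.2)
  fit <- fit_gbr(X, y, nrounds = 300, depth = 4)
  sh <- shapley_attributions(fit, X)
  rho <- setNames(as.numeric(cor(X, y, method = "spearman")), colnames(X))

  # interaction drivers dominate the Shapley ranking but not |rho|
  expect_true(all(c("x1", "x2") %in% head(sh$ranking$feature, 3)))
  expect_equal(names(which.max(abs(rho))), "x4")
  out <- importance_correlation_overlap(sh, rho, k = 2)
  expect_lt(out$overlap, 2)
  expect_equal(nrow(out$table), 2)

  # identical rankings give full overlap; k = 0 gives none
  rho_same <- setNames(rev(seq_len(6)) / 10, sh$ranking$feature)
  expect_equal(importance_correlation_overlap(sh, rho_same, k = 6)$overlap, 6)
  expect_equal(importance_correlation_overlap(sh, rho, k = 0)$overlap, 0)
  expect_error(importance_correlation_overlap(sh, rho, k = 99), "exceeds")
})

test_that("the sampling fallback approximates attribution for non-tree models", {
  set.seed(14)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] + rnorm(40, 0.05)
  lr <- fit_model(model_spec("LR", interactions = FALSE), X, y)
  sh <- shapley_attributions(lr, X[1:5, ], nsim = 32, seed = 2)
  expect_equal(sh$method, "sampling")
  # linear model: phi_j ~ beta_j * (x_j - mean(x_j)); check the dominant one
  expect_gt(cor(sh$values[, "a"], X[1:5, "a"]), 0.95)
})
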