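sim_xy <- function(n, p, fun, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  list(X = X, y = fun(X) + rnorm(n, 0, noise))
}

test_that("interaction features enumerate pairwise products", {
  X <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xd <- build_features(X, TRUE)
  expect_equal(ncol(Xd), 3 + 3)
  expect_equal(colnames(Xd), c("a", "b", "c", "a:b", "a:c", "b:c"))
  expect_equal(Xd[, "a:b"], X[, "a"] * X[, "b"])
  expect_identical(build_features(X, FALSE), X)

  wide <- matrix(0, 2, 231, dimnames = list(NULL, sprintf("p%03d", 1:231)))
  expect_equal(ncol(build_features(wide, TRUE)), 231 + choose(231, 2))
})

test_that("plain linear regression recovers a noiseless linear target", {
  d <- sim_xy(60, 3, function(X) 2 * X[, 1] + 1)
  spec <- model_spec("LR", interactions = FALSE)
  fit <- fit_model(spec, d$X[1:40, ], d$y[1:40])
  expect_equal(r_squared(d$y[41:60], predict(fit, d$X[41:60, ])), 1,
               tolerance = 1e-9)
})

test_that("boosted trees out-predict interaction-free linear models on a pure interaction", {
  d <- sim_xy(500, 4, function(X) X[, 1] * X[, 2], noise = 0.1)
  tr <- 1:350; te <- 351:500
  gbr <- fit_model(model_spec("GBR", grid = list(list(nrounds = 200,
                                                      max_depth = 3,
                                                      eta = 0.1))),
                   d$X[tr, ], d$y[tr])
  lr <- fit_model(model_spec("LR", interactions = FALSE), d$X[tr, ], d$y[tr])
  r2_gbr <- r_squared(d$y[te], predict(gbr, d$X[te, ]))
  r2_lr <- r_squared(d$y[te], predict(lr, d$X[te, ]))
  expect_gt(r2_gbr, r2_lr)
  expect_gt(r2_gbr, 0.5)
})

test_that("every family fits, predicts, and is deterministic under its seed", {
  d <- sim_xy(60, 5, function(X) X[, 1] + 0.5 * X[, 2]^2, noise = 0.2)
  tiny_grids <- list(
    LR = NULL, Lasso = list(list(lambda = 0.05)),
    PLSR = list(list(ncomp = 3)), ABR = list(list(n_estimators = 20, maxdepth = 3)),
    ET = list(list(num_trees = 50, mtry_frac = 0.5)),
    GBR = list(list(nrounds = 50, max_depth = 3, eta = 0.1)),
    RF = list(list(num_trees = 50, mtry_frac = 0.5)),
    XGBR = list(list(nrounds = 50, max_depth = 3, eta = 0.3)),
    SVR = list(list(cost = 1, gamma_mult = 1)),
    ANN = list(list(size = 4, decay = 0.1)))
  for (fam in names(tiny_grids)) {
    spec <- model_spec(fam, grid = tiny_grids[[fam]], seed = 3)
    f1 <- fit_model(spec, d$X[1:45, ], d$y[1:45])
    f2 <- fit_model(spec, d$X[1:45, ], d$y[1:45])
    p1 <- predict(f1, d$X[46:60, ])
    expect_identical(p1, predict(f2, d$X[46:60, ]))
    expect_true(all(is.finite(p1)))
  }
})

test_that("constant targets are rejected by descriptor name", {
  d <- sim_xy(30, 3, function(X) X[, 1])
  Y <- cbind(ok = d$y, flat = 1)
  expect_error(fit_model(model_spec("LR", interactions = FALSE), d$X, Y),
               "flat")
})

test_that("overparameterized linear regression overfits to training R2 = 1", {
  # n << p once interactions are included: the classic overfit diagnostic
  d <- sim_xy(40, 12, function(X) X[, 1], noise = 0.5)
  fit <- fit_model(model_spec("LR", interactions = TRUE), d$X, d$y)
  expect_equal(r_squared(d$y, predict(fit, d$X)), 1, tolerance = 1e-6)
})

test_that("suite evaluation ranks models with midranks and averages R2", {
  d <- sim_xy(80, 3, function(X) X[, 1], noise = 0.3)
  set.seed(4)
  Y <- cbind(d1 = d$y, d2 = d$X[, 2] + rnorm(80, 0, 0.3))
  tr <- 1:60; te <- 61:80
  good <- fit_model(model_spec("LR", interactions = FALSE),
                    d$X[tr, ], Y[tr, ])
  bad_spec <- model_spec("Lasso", grid = list(list(lambda = 50)),
                         interactions = FALSE)
  bad <- fit_model(bad_spec, d$X[tr, ], Y[tr, ])
  res <- evaluate_suite(list(good = good, bad = bad), d$X[te, ], Y[te, ],
                        d$X[tr, ], Y[tr, ])
  expect_equal(unname(res$avg_rank), c(1, 2))
  expect_equal(unname(res$multi_output),
               unname(rowMeans(res$per_descriptor)))
  # midrank conservation: ranks per descriptor sum to M(M+1)/2
  expect_true(all(colSums(res$ranks) == 3))

  # an exact tie takes the midrank
  res_tie <- evaluate_suite(list(a = good, b = good), d$X[te, ], Y[te, ])
  expect_equal(unname(res_tie$avg_rank), c(1.5, 1.5))

  # aggregate R2 equals hand-computed 1 - SSE/SST per descriptor, averaged
  P <- predict(good, d$X[te, ])
  hand <- mean(vapply(1:2, function(j) {
    1 - sum((Y[te, j] - P[, j])^2) / sum((Y[te, j] - mean(Y[te, j]))^2)
  }, numeric(1)))
  expect_equal(unname(res$multi_output["good"]), hand)
})

test_that("stability runs are reproducible and track planted structure", {
  d <- sim_xy(120, 8, function(X) X[, 1] * X[, 2] + X[, 3], noise = 0.2)
  beers <- data.frame(beer_id = sprintf("b%03d", 1:120),
                      style = rep(c("A", "B", "C"), each = 40), abv = 5)
  vals <- exp(d$X)  # strictly positive concentrations
  rownames(vals) <- beers$beer_id
  chem <- compound_matrix(beers, vals)
  y <- setNames(d$y, beers$beer_id)
  spec <- model_spec("GBR", grid = list(list(nrounds = 100, max_depth = 3,
                                             eta = 0.1)))
  out <- stability_runs(spec, chem, y, n_iter = 5, top_k = 3, seed = 50)
  out2 <- stability_runs(spec, chem, y, n_iter = 5, top_k = 3, seed = 50)
  expect_identical(out$top_lists, out2$top_lists)
  expect_gt(var(out$r2), 0)  # distinct splits give a non-degenerate spread
  # the dominant planted drivers appear in every top-3
  hits <- vapply(out$top_lists, function(tl)
    all(c("x1", "x2") %in% tl) || "x3" %in% tl, logical(1))
  expect_true(all(hits))
})

test_that("dataset-identifier experiments expose provenance shifts", {
  d <- sim_xy(150, 6, function(X) X[, 1], noise = 0.2)
  # identical datasets: the identifier carries nothing
  same <- augmented_experiments(d$X, d$y, d$y, mode = "combined+identifier",
                                seed = 2)
  expect_lt(same$added_features$mdi, 0.02)
  # a constant target offset makes the identifier the top feature
  offset <- augmented_experiments(d$X, d$y, d$y + 3,
                                  mode = "combined+identifier", seed = 2)
  expect_equal(offset$added_features$feature, "dataset_id")
  expect_equal(offset$added_features$rank, 1)

  # style one-hots on a style-balanced target stay unimportant
  styles <- rep(c("A", "B", "C"), each = 50)
  st <- augmented_experiments(d$X, d$y, mode = "style_onehot",
                              styles = styles, seed = 2)
  expect_false(any(st$added_features$feature %in%
                     head(st$importance$feature, 3)))
})
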