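.FAMILIES <- c("LR", "Lasso", "PLSR", "ABR", "ET", "GBR", "RF", "XGBR",
               "SVR", "ANN")

#' Model specification
#'
#' Names one of the ten regression families and its hyperparameter grid.
#' First-order interaction features are available for the two plain linear
#' families only (LR, Lasso), matching how those models are used in the
#' benchmark.
#'
#' @param family one of LR, Lasso, PLSR, ABR, ET, GBR, RF, XGBR, SVR, ANN.
#' @param grid list of named hyperparameter lists; `NULL` picks the
#'   built-in default grid (see [default_grid()]).
#' @param interactions append pairwise product features before fitting.
#' @param seed integer seed for the family's stochastic parts.
#' @return an object of class `flv_spec`.
#' @export
model_spec <- function(family, grid = NULL, interactions = NULL, seed = 1) {
  family <- match.arg(family, .FAMILIES)
  if (is.null(interactions)) interactions <- family %in% c("LR", "Lasso")
  stop_if(interactions && !family %in% c("LR", "Lasso"),
          "interaction features are only used with LR and Lasso")
  if (!is.null(grid)) stop_if(length(grid) == 0, "grid must be non-empty")
  structure(list(family = family, grid = grid, interactions = interactions,
                 seed = seed), class = "flv_spec")
}

#' Default hyperparameter grids
#'
#' Modest desk-scale grids per family: boosted trees search tree count
#' {100, 300}, depth {3, 6} and learning rate {0.05, 0.1}; forests search
#' tree count and mtry; Lasso a log-spaced lambda grid; PLSR the component
#' count; SVR RBF cost/gamma log grids; the single-hidden-layer network
#' its width and weight decay.
#'
#' @param family model family name.
#' @param p number of predictors (used for mtry / gamma scaling).
#' @return list of named hyperparameter lists.
#' @export
default_grid <- function(family, p = 100) {
  expand_list <- function(...) {
    g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  switch(family,
    LR = list(list()),
    Lasso = expand_list(lambda = 10^seq(-3, 0.5, length.out = 8)),
    PLSR = expand_list(ncomp = c(2, 4, 6, 8, 12, 16, 20)),
    ABR = expand_list(n_estimators = c(50, 100), maxdepth = 3),
    ET = expand_list(num_trees = c(100, 300),
                     mtry_frac = c(0.1, 0.33)),
    GBR = expand_list(nrounds = c(100, 300), max_depth = c(3, 6),
                      eta = c(0.05, 0.1)),
    RF = expand_list(num_trees = c(100, 300), mtry_frac = c(0.1, 0.33)),
    XGBR = expand_list(nrounds = c(100, 300), max_depth = c(3, 6),
                       eta = c(0.05, 0.1)),
    SVR = expand_list(cost = c(0.1, 1, 10), gamma_mult = c(0.1, 1, 10)),
    ANN = expand_list(size = c(8, 16, 32), decay = c(0.1, 1)))
}

#' Append first-order interaction features
#'
#' All pairwise products `x_i * x_j` (i < j), no squares, named `a:b`.
#' Built after standardization; product terms are never re-standardized so
#' they stay interpretable on the z-scale.
#'
#' @param X standardized numeric matrix.
#' @param interactions logical; `FALSE` returns `X` unchanged.
#' @return numeric matrix with `p + choose(p, 2)` columns when enabled.
#' @export
build_features <- function(X, interactions = TRUE) {
  if (!interactions) return(X)
  p <- ncol(X)
  if (p < 2) return(X)
  pairs <- combn(p, 2)
  prod_m <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
  colnames(prod_m) <- paste(colnames(X)[pairs[1, ]],
                            colnames(X)[pairs[2, ]], sep = ":")
  cbind(X, prod_m)
}

# ---- family engines -------------------------------------------------------
# each engine: fit(X, y, params, seed) -> fit object; pred(fit, X) -> numeric

.engine <- function(family, p) {
  switch(family,
    LR = list(
      fit = function(X, y, params, seed) {
        f <- lm.fit(cbind(`(Intercept)` = 1, X), y)
        cf <- f$coefficients
        cf[is.na(cf)] <- 0
        list(coef = cf)
      },
      pred = function(fit, X) as.numeric(cbind(1, X) %*% fit$coef)),
    Lasso = list(
      fit = function(X, y, params, seed) {
        glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda,
                       standardize = FALSE)
      },
      pred = function(fit, X) as.numeric(predict(fit, X))),
    PLSR = list(
      fit = function(X, y, params, seed) {
        nc <- min(params$ncomp, ncol(X) - 1, nrow(X) - 1)
        mixOmics::pls(X, y, ncomp = nc, mode = "regression")
      },
      pred = function(fit, X) {
        pr <- predict(fit, X)$predict
        as.numeric(pr[, 1, dim(pr)[3]])
      }),
    ABR = list(
      fit = function(X, y, params, seed) {
        set.seed(seed)
        ada_boost_r2(X, y, n_estimators = params$n_estimators,
                     maxdepth = params$maxdepth)
      },
      pred = function(fit, X) predict(fit, X)),
    ET = list(
      fit = function(X, y, params, seed) {
        ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                       mtry = max(1, floor(params$mtry_frac * ncol(X))),
                       splitrule = "extratrees", num.random.splits = 1,
                       importance = "impurity", seed = seed,
                       num.threads = 1)
      },
      pred = function(fit, X)
        predict(fit, data = X, num.threads = 1)$predictions),
    GBR = list(
      fit = function(X, y, params, seed) {
        set.seed(seed)
        xgboost::xgb.train(
          params = list(max_depth = params$max_depth, eta = params$eta,
                        lambda = 0, alpha = 0, tree_method = "exact",
                        subsample = 1, colsample_bytree = 1,
                        base_score = mean(y), nthread = 1, seed = seed),
          data = xgboost::xgb.DMatrix(X, label = y),
          nrounds = params$nrounds, verbose = 0)
      },
      pred = function(fit, X) predict(fit, X)),
    RF = list(
      fit = function(X, y, params, seed) {
        ranger::ranger(x = X, y = y, num.trees = params$num_trees,
                       mtry = max(1, floor(params$mtry_frac * ncol(X))),
                       importance = "impurity", seed = seed,
                       num.threads = 1)
      },
      pred = function(fit, X)
        predict(fit, data = X, num.threads = 1)$predictions),
    XGBR = list(
      fit = function(X, y, params, seed) {
        set.seed(seed)
        xgboost::xgb.train(
          params = list(max_depth = params$max_depth, eta = params$eta,
                        base_score = mean(y), nthread = 1, seed = seed),
          data = xgboost::xgb.DMatrix(X, label = y),
          nrounds = params$nrounds, verbose = 0)
      },
      pred = function(fit, X) predict(fit, X)),
    SVR = list(
      fit = function(X, y, params, seed) {
        e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                   cost = params$cost, gamma = params$gamma_mult / ncol(X),
                   scale = FALSE)
      },
      pred = function(fit, X) as.numeric(predict(fit, X))),
    ANN = list(
      fit = function(X, y, params, seed) {
        set.seed(seed)
        nnet::nnet(X, y, size = params$size, decay = params$decay,
                   linout = TRUE, maxit = 300, trace = FALSE,
                   MaxNWts = 200000)
      },
      pred = function(fit, X) as.numeric(predict(fit, X))))
}

#' AdaBoost.R2 regressor
#'
#' Boosted regression trees with the adaptive reweighting scheme of
#' Drucker's AdaBoost.R2 (linear loss): each round fits a depth-limited
#' tree to a weighted bootstrap of the data, samples are reweighted by
#' their relative absolute error, and the prediction is the weighted
#' median over rounds. Written here because no AdaBoost regression
#' implementation ships with the environment's R stack.
#'
#' @param X numeric matrix of predictors.
#' @param y numeric response.
#' @param n_estimators maximum number of boosting rounds.
#' @param maxdepth base-tree depth.
#' @return an object of class `flv_abr` with a `predict` method.
#' @export
ada_boost_r2 <- function(X, y, n_estimators = 50, maxdepth = 3) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  betas <- numeric(0)
  df <- data.frame(y = y, X, check.names = FALSE)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, xval = 0,
                          minsplit = 5))
    pred <- predict(fit, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) {
      learners[[m]] <- fit
      betas[m] <- 1e-10
      break
    }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) break
    beta <- lbar / (1 - lbar)
    learners[[m]] <- fit
    betas[m] <- beta
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  stop_if(length(learners) == 0, "AdaBoost.R2 could not fit any learner")
  structure(list(learners = learners, betas = betas), class = "flv_abr")
}

#' @export
predict.flv_abr <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) {
    newdata <- data.frame(newdata, check.names = FALSE)
  }
  P <- vapply(object$learners, function(f) predict(f, newdata),
              numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  lw <- log(1 / object$betas)
  apply(P, 1, function(row) {
    o <- order(row)
    cw <- cumsum(lw[o])
    row[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

# 5-fold CV grid search for a single response
.grid_search <- function(engine, X, y, grid, folds, seed) {
  if (length(grid) == 1) {
    return(list(params = grid[[1]], cv = NA_real_,
                cv_table = data.frame(score = NA_real_)))
  }
  scores <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    r2s <- numeric(max(folds))
    for (k in seq_len(max(folds))) {
      tr <- folds != k
      fit <- engine$fit(X[tr, , drop = FALSE], y[tr], grid[[gi]],
                        seed = seed + 1000 * k)
      pred <- engine$pred(fit, X[!tr, , drop = FALSE])
      r2s[k] <- tryCatch(r_squared(y[!tr], pred), error = function(e) NA_real_)
    }
    scores[gi] <- mean(r2s, na.rm = TRUE)
  }
  best <- which.max(scores)
  list(params = grid[[best]], cv = scores[best],
       cv_table = data.frame(config = seq_along(grid), score = scores))
}

#' Fit one model family with cross-validated grid search
#'
#' Hyperparameters are chosen by five-fold cross-validated grid search on
#' the training data, maximizing the mean R-squared across folds; the
#' winning configuration is refit on the full training set. Multi-column
#' responses fit one model per column (sharing the grid search machinery),
#' giving a multi-output model in the usual per-target sense.
#'
#' @param spec an [model_spec()].
#' @param X standardized training predictor matrix.
#' @param Y numeric response vector, or matrix with one column per
#'   sensory descriptor.
#' @param folds number of CV folds.
#' @return an object of class `flv_model` with a `predict` method.
#' @export
fit_model <- function(spec, X, Y, folds = 5) {
  stopifnot(inherits(spec, "flv_spec"))
  X <- as.matrix(X)
  stop_if(nrow(X) < 10, "need at least 10 training rows")
  Xd <- build_features(X, spec$interactions)
  one_col <- is.null(dim(Y))
  Ym <- if (one_col) matrix(Y, ncol = 1, dimnames = list(NULL, "y")) else as.matrix(Y)
  const <- apply(Ym, 2, function(v) var(v) == 0)
  stop_if(any(const), "constant target descriptor: ",
          paste(colnames(Ym)[const], collapse = ", "))
  grid <- spec$grid %||% default_grid(spec$family, p = ncol(Xd))
  engine <- .engine(spec$family, ncol(Xd))
  set.seed(spec$seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(Xd)))
  fits <- vector("list", ncol(Ym))
  best <- vector("list", ncol(Ym))
  for (j in seq_len(ncol(Ym))) {
    gs <- .grid_search(engine, Xd, Ym[, j], grid, fold_id, spec$seed)
    fits[[j]] <- engine$fit(Xd, Ym[, j], gs$params, seed = spec$seed)
    best[[j]] <- gs
  }
  names(fits) <- names(best) <- colnames(Ym)
  structure(list(spec = spec, fits = fits, search = best,
                 feature_names = colnames(Xd),
                 input_names = colnames(X), single = one_col),
            class = "flv_model")
}

#' @export
predict.flv_model <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  newX <- newX[, object$input_names, drop = FALSE]
  Xd <- build_features(newX, object$spec$interactions)
  engine <- .engine(object$spec$family, ncol(Xd))
  P <- vapply(object$fits, function(f) engine$pred(f, Xd),
              numeric(nrow(Xd)))
  P <- matrix(P, nrow = nrow(Xd), dimnames = list(NULL, names(object$fits)))
  if (object$single) as.numeric(P[, 1]) else P
}

#' Evaluate a suite of fitted models
#'
#' Computes per-descriptor test R-squared for every model, the
#' multi-output R-squared (uniform average over descriptors), and the
#' average rank: per descriptor the models are ranked 1..M by test
#' R-squared (midranks on ties, rank 1 best) and ranks are averaged per
#' model. Training R-squared is reported when training data is supplied
#' (overfit diagnostics).
#'
#' @param models named list of `flv_model` objects sharing one split.
#' @param X_test,Y_test held-out predictors and targets.
#' @param X_train,Y_train optional training data for train R-squared.
#' @return an object of class `flv_bench`.
#' @export
evaluate_suite <- function(models, X_test, Y_test,
                           X_train = NULL, Y_train = NULL) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  Ym <- if (is.null(dim(Y_test))) matrix(Y_test, ncol = 1,
                                         dimnames = list(NULL, "y"))
        else as.matrix(Y_test)
  M <- length(models)
  r2 <- matrix(NA_real_, M, ncol(Ym),
               dimnames = list(names(models), colnames(Ym)))
  for (m in seq_len(M)) {
    P <- predict(models[[m]], X_test)
    P <- if (is.null(dim(P))) matrix(P, ncol = 1) else P
    for (j in seq_len(ncol(Ym))) r2[m, j] <- r_squared(Ym[, j], P[, j])
  }
  ranks <- apply(r2, 2, rank_desc)
  ranks <- matrix(ranks, nrow = M, dimnames = dimnames(r2))
  avg_rank <- rowMeans(ranks)
  train_r2 <- NULL
  if (!is.null(X_train)) {
    Ytr <- if (is.null(dim(Y_train))) matrix(Y_train, ncol = 1) else as.matrix(Y_train)
    train_r2 <- vapply(models, function(mod) {
      P <- predict(mod, X_train)
      P <- if (is.null(dim(P))) matrix(P, ncol = 1) else P
      mean(vapply(seq_len(ncol(Ytr)),
                  function(j) r_squared(Ytr[, j], P[, j]), numeric(1)))
    }, numeric(1))
  }
  structure(list(per_descriptor = r2, multi_output = rowMeans(r2),
                 avg_rank = avg_rank, ranks = ranks, train_r2 = train_r2),
            class = "flv_bench")
}

#' @export
print.flv_bench <- function(x, ...) {
  df <- data.frame(model = rownames(x$per_descriptor),
                   R2 = round(x$multi_output, 3),
                   avg_rank = round(x$avg_rank, 2))
  if (!is.null(x$train_r2)) df$train_R2 <- round(x$train_r2, 3)
  cat("<flv_bench> test performance\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Stability of fits and importance rankings across random splits
#'
#' Repeats split + preprocess + fit + Shapley dissection over `n_iter`
#' distinct seeds and tallies how often each feature lands in the top-k
#' aggregate importance, together with the distribution of test
#' R-squared.
#'
#' @param spec an [model_spec()] for a tree family (fixed hyperparameters
#'   recommended: pass a singleton grid).
#' @param chem a [compound_matrix()].
#' @param y named numeric target vector (names = beer ids).
#' @param n_iter number of iterations (the study used 100).
#' @param top_k size of the importance head to tally.
#' @param train_frac split fraction.
#' @param seed base seed; iteration i uses `seed + i`.
#' @return list with `freq` (named top-k frequency), `r2` (per-iteration
#'   test R-squared) and `top_lists`.
#' @export
stability_runs <- function(spec, chem, y, n_iter = 100, top_k = 10,
                           train_frac = 0.7, seed = 1) {
  stopifnot(inherits(chem, "flv_chem"), n_iter >= 2)
  y <- y[rownames(chem$values)]
  stop_if(anyNA(y), "target must cover every beer in the chemistry")
  tops <- vector("list", n_iter)
  r2 <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    si <- seed + i
    sp <- split_stratified(chem, train_frac, seed = si)
    state <- preprocess_fit(chem, sp$train)
    Xtr <- preprocess_apply(state, chem$values[sp$train, , drop = FALSE])
    Xte <- preprocess_apply(state, chem$values[sp$test, , drop = FALSE])
    spec_i <- spec
    spec_i$seed <- si
    fit <- fit_model(spec_i, Xtr, y[sp$train])
    r2[i] <- r_squared(y[sp$test], predict(fit, Xte))
    sh <- shapley_attributions(fit, Xtr)
    tops[[i]] <- head(sh$ranking$feature, top_k)
  }
  freq <- sort(table(unlist(tops)), decreasing = TRUE)
  list(freq = freq, r2 = r2, top_lists = tops)
}

#' Combined-dataset and style-feature experiments
#'
#' Three ablations around dataset provenance and style encoding:
#' `combined` stacks two target sources over the same predictor space;
#' `combined+identifier` additionally adds a binary source feature;
#' `style_onehot` adds one-hot style columns to a single dataset. Returns
#' test performance and the importance rank of every added feature, so
#' one can check whether provenance or style dominates the model.
#'
#' @param X predictor matrix (beers x features, preprocessed).
#' @param y_a,y_b the two target vectors (same beers); `y_b = NULL` for
#'   `style_onehot`.
#' @param mode one of "combined", "combined+identifier", "style_onehot".
#' @param styles character vector of per-beer styles (style_onehot mode).
#' @param spec model used; default GBR with a singleton grid.
#' @param seed split/fit seed.
#' @param train_frac split fraction.
#' @return list with `r2`, `importance` (full MDI table) and
#'   `added_features` (feature, mdi, rank).
#' @export
augmented_experiments <- function(X, y_a, y_b = NULL,
                                  mode = c("combined", "combined+identifier",
                                           "style_onehot"),
                                  styles = NULL, spec = NULL, seed = 1,
                                  train_frac = 0.7) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(spec)) {
    spec <- model_spec("GBR", grid = list(list(nrounds = 300, max_depth = 6,
                                               eta = 0.1)), seed = seed)
  }
  added <- character(0)
  if (mode %in% c("combined", "combined+identifier")) {
    stop_if(is.null(y_b), "combined modes need two target vectors")
    stop_if(length(y_a) != nrow(X) || length(y_b) != nrow(X),
            "targets must match the predictor rows")
    Xc <- rbind(X, X)
    y <- c(y_a, y_b)
    if (mode == "combined+identifier") {
      Xc <- cbind(Xc, dataset_id = rep(c(0, 1), each = nrow(X)))
      added <- "dataset_id"
    }
  } else {
    stop_if(is.null(styles), "style_onehot mode needs styles")
    oh <- model.matrix(~ 0 + factor(styles))
    colnames(oh) <- paste0("style_", levels(factor(styles)))
    Xc <- cbind(X, oh)
    y <- y_a
    added <- colnames(oh)
  }
  set.seed(seed)
  n <- nrow(Xc)
  test <- sample.int(n, round(n * (1 - train_frac)))
  tr <- setdiff(seq_len(n), test)
  fit <- fit_model(spec, Xc[tr, , drop = FALSE], y[tr])
  r2 <- r_squared(y[test], predict(fit, Xc[test, , drop = FALSE]))
  imp <- mdi_ranking(fit)
  af <- imp[imp$feature %in% added, , drop = FALSE]
  list(r2 = r2, importance = imp, added_features = af)
}
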