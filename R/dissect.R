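# parse an xgboost booster into flat node arrays for the C++ kernels
.xgb_forest <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  dt$row <- seq_len(nrow(dt)) - 1L
  id2row <- setNames(dt$row, dt$ID)
  is_leaf <- dt$Feature == "Leaf"
  feat <- ifelse(is_leaf, -1L,
                 match(dt$Feature, feature_names) - 1L)
  stop_if(any(is.na(feat) & !is_leaf),
          "tree references a feature absent from feature_names")
  list(feature = as.integer(feat),
       threshold = ifelse(is_leaf, 0, dt$Split),
       yes = as.integer(ifelse(is_leaf, -1L, id2row[dt$Yes])),
       no = as.integer(ifelse(is_leaf, -1L, id2row[dt$No])),
       value = ifelse(is_leaf, dt$Gain, 0),
       cover = dt$Cover,
       roots = as.integer(dt$row[dt$Node == 0]))
}

.xgb_base_score <- function(booster) {
  cfg <- xgboost::xgb.config(booster)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

.is_xgb_model <- function(model) {
  inherits(model, "xgb.Booster")
}

# pull the per-descriptor fits out of an flv_model (or pass raw fits through)
.tree_fits <- function(model) {
  if (inherits(model, "flv_model")) {
    list(fits = model$fits, family = model$spec$family,
         features = model$feature_names)
  } else {
    list(fits = list(y = model), family = NA_character_, features = NULL)
  }
}

#' Impurity-based feature importance (MDI)
#'
#' Mean-decrease-in-impurity importance from a fitted tree ensemble,
#' normalized to sum to 1, in descending order with lexicographic
#' tie-breaks. Multi-descriptor models average the per-descriptor
#' normalized importances.
#'
#' @param model an `flv_model` of a tree family (ABR, ET, GBR, RF, XGBR)
#'   or a raw xgboost/ranger fit.
#' @return data.frame with columns `feature`, `mdi`, `rank`.
#' @export
mdi_ranking <- function(model) {
  tf <- .tree_fits(model)
  imp_one <- function(fit) {
    if (.is_xgb_model(fit)) {
      feats <- tf$features %||% NULL
      it <- xgboost::xgb.importance(model = fit)
      v <- setNames(it$Gain, it$Feature)
    } else if (inherits(fit, "ranger")) {
      v <- fit$variable.importance
    } else if (inherits(fit, "flv_abr")) {
      vs <- lapply(fit$learners, function(l) l$variable.importance)
      all_f <- unique(unlist(lapply(vs, names)))
      v <- setNames(rep(0, length(all_f)), all_f)
      for (x in vs) v[names(x)] <- v[names(x)] + x
    } else {
      stop("impurity importance needs a tree-based model", call. = FALSE)
    }
    v
  }
  feats <- tf$features
  agg <- NULL
  for (fit in tf$fits) {
    v <- imp_one(fit)
    if (is.null(feats)) feats <- names(v)
    full <- setNames(rep(0, length(feats)), feats)
    full[names(v)[names(v) %in% feats]] <- v[names(v) %in% feats]
    if (sum(full) > 0) full <- full / sum(full)
    agg <- if (is.null(agg)) full else agg + full
  }
  agg <- agg / length(tf$fits)
  ord <- order(-agg, names(agg))
  data.frame(feature = names(agg)[ord], mdi = unname(agg[ord]),
             rank = seq_along(agg), stringsAsFactors = FALSE)
}

#' Shapley attributions for a fitted model
#'
#' For gradient-boosted models the exact path-dependent TreeSHAP algorithm
#' is run in double precision over the parsed trees, so local accuracy
#' (base value + row sum = model prediction) holds to numerical precision
#' on every sample. Other families fall back to a seeded Monte Carlo
#' permutation approximation over a background sample. The aggregate
#' importance is the mean absolute attribution per feature (optionally the
#' maximum).
#'
#' @param model an `flv_model` (single-descriptor) or raw xgboost booster.
#' @param X matrix of samples to attribute (model feature space for raw
#'   boosters, input space for `flv_model`s).
#' @param aggregate "mean_abs" (default) or "max_abs".
#' @param nsim Monte Carlo permutations per sample for the sampling
#'   fallback.
#' @param seed seed for the sampling fallback.
#' @return an object of class `flv_shap`: list with `values` (samples x
#'   features), `base_value`, `prediction` (the model function evaluated in
#'   double precision on each sample; `base_value + rowSums(values)` equals
#'   it to numerical precision for tree models), and `ranking`.
#' @export
shapley_attributions <- function(model, X, aggregate = c("mean_abs", "max_abs"),
                                 nsim = 64, seed = 1) {
  aggregate <- match.arg(aggregate)
  X <- as.matrix(X)
  if (inherits(model, "flv_model")) {
    stop_if(!model$single,
            "attribute one descriptor at a time (single-output model)")
    X <- X[, model$input_names, drop = FALSE]
    Xd <- build_features(X, model$spec$interactions)
    fit <- model$fits[[1]]
    feats <- model$feature_names
  } else {
    fit <- model
    Xd <- X
    feats <- colnames(X)
  }
  if (.is_xgb_model(fit)) {
    forest <- .xgb_forest(fit, feats)
    res <- .treeshap_cpp(Xd[, feats, drop = FALSE], forest$feature,
                         forest$threshold, forest$yes, forest$no,
                         forest$value, forest$cover, forest$roots,
                         .xgb_base_score(fit))
    vals <- res$phi
    dimnames(vals) <- list(rownames(Xd), feats)
    base <- res$base_value
    prediction <- .treepredict_cpp(Xd[, feats, drop = FALSE], forest$feature,
                                   forest$threshold, forest$yes, forest$no,
                                   forest$value, forest$cover, forest$roots,
                                   .xgb_base_score(fit))
    method <- "treeshap_exact"
  } else {
    predfun <- function(M) {
      if (inherits(model, "flv_model")) {
        engine <- .engine(model$spec$family, ncol(M))
        engine$pred(fit, M)
      } else {
        predict(fit, M)
      }
    }
    sh <- .sampling_shap(predfun, Xd, Xd, nsim = nsim, seed = seed)
    vals <- sh$values
    colnames(vals) <- feats
    base <- sh$base_value
    prediction <- predfun(Xd)
    method <- "sampling"
  }
  imp <- if (aggregate == "mean_abs") colMeans(abs(vals)) else
    apply(abs(vals), 2, max)
  ord <- order(-imp, colnames(vals))
  ranking <- data.frame(feature = colnames(vals)[ord],
                        importance = unname(imp[ord]),
                        rank = seq_along(imp), stringsAsFactors = FALSE)
  structure(list(values = vals, base_value = base, ranking = ranking,
                 prediction = as.numeric(prediction), method = method),
            class = "flv_shap")
}

#' @export
print.flv_shap <- function(x, ...) {
  cat(sprintf("<flv_shap> %d samples x %d features (%s), base value %.4f\n",
              nrow(x$values), ncol(x$values), x$method, x$base_value))
  print(head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

# Strumbelj-Kononenko Monte Carlo Shapley sampling over a background set
.sampling_shap <- function(predfun, X, background, nsim = 64, seed = 1) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  base <- mean(predfun(background))
  vals <- matrix(0, n, p)
  for (i in seq_len(n)) {
    x <- X[i, ]
    for (s in seq_len(nsim)) {
      perm <- sample.int(p)
      b <- background[sample.int(nrow(background), 1), ]
      cur <- b
      prev_pred <- NULL
      built <- rbind(cur)
      for (j in perm) {
        cur[j] <- x[j]
        built <- rbind(built, cur)
      }
      preds <- predfun(built)
      for (k in seq_len(p)) {
        vals[i, perm[k]] <- vals[i, perm[k]] + (preds[k + 1] - preds[k]) / nsim
      }
    }
  }
  list(values = vals, base_value = base)
}

#' Partial dependence of a model on one or two features
#'
#' `PD(v)` is the mean model prediction over the sample with the chosen
#' feature(s) clamped to `v`; the grid is placed on equally spaced
#' quantiles of the observed feature, which is robust to the long right
#' tails of concentration data.
#'
#' @param model `flv_model` or raw fit with a predict path through
#'   [shapley_attributions()]'s conventions.
#' @param X sample matrix (input space).
#' @param features one or two feature names.
#' @param grid number of grid points per feature.
#' @return data.frame with the grid value(s) and `pd`.
#' @export
partial_dependence <- function(model, X, features, grid = 20) {
  stop_if(grid < 2, "grid must have at least 2 points")
  X <- as.matrix(X)
  stop_if(!all(features %in% colnames(X)),
          "unknown feature: ",
          paste(setdiff(features, colnames(X)), collapse = ", "))
  stop_if(length(features) > 2, "one or two features only")
  predfun <- function(M) {
    p <- predict(model, M)
    if (is.matrix(p)) p[, 1] else p
  }
  grids <- lapply(features, function(f) {
    g <- unique(quantile(X[, f], probs = seq(0, 1, length.out = grid),
                         type = 7, na.rm = TRUE))
    if (length(g) == 1) warning("constant feature '", f,
                                "': single-point curve")
    g
  })
  names(grids) <- features
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  pd <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    Xc <- X
    for (f in features) Xc[, f] <- combos[i, f]
    pd[i] <- mean(predfun(Xc))
  }
  out <- combos
  out$pd <- pd
  out
}

#' Overlap between Shapley importance and marginal correlation
#'
#' Compares the top-k features by aggregate |Shapley| against the top-k
#' by absolute Spearman correlation with the target, returning the overlap
#' count and a side-by-side table (each top-k Shapley feature with its
#' rho and the rank of that rho among all features) -- the model-vs-
#' conventional-statistics comparison.
#'
#' @param shap an `flv_shap` (or its `ranking` data.frame).
#' @param rho named numeric vector of Spearman correlations between each
#'   feature and the target.
#' @param k head size.
#' @return list with `overlap` (count) and `table`.
#' @export
importance_correlation_overlap <- function(shap, rho, k = 15) {
  ranking <- if (inherits(shap, "flv_shap")) shap$ranking else shap
  feats <- ranking$feature
  stop_if(k > length(feats), "k exceeds the number of features")
  rho <- rho[feats]
  stop_if(anyNA(rho), "rho must cover every ranked feature")
  if (k == 0) {
    return(list(overlap = 0L,
                table = data.frame(feature = character(0), shap_rank = integer(0),
                                   rho = numeric(0), rho_rank = integer(0))))
  }
  rho_rank <- rank_desc(abs(rho))
  top_shap <- head(feats, k)
  top_rho <- feats[order(rho_rank, feats)][seq_len(k)]
  tab <- data.frame(feature = top_shap,
                    shap_rank = seq_len(k),
                    rho = unname(rho[top_shap]),
                    rho_rank = unname(rho_rank[top_shap]),
                    stringsAsFactors = FALSE)
  list(overlap = length(intersect(top_shap, top_rho)), table = tab)
}
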