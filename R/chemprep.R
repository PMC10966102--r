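#' Compound matrix container
#'
#' Bundles a beers-by-properties concentration matrix with per-beer metadata
#' (style, ABV, optional price) and per-property metadata (origin class,
#' aggregate flag). This is the predictor space for all downstream models.
#'
#' @param beers data.frame with columns `beer_id`, `style`, `abv` and
#'   optionally `price_per_l`.
#' @param values numeric matrix, one row per beer (rownames = beer ids),
#'   one column per chemical property. `NA` marks a missing measurement.
#' @param property_meta optional data.frame with columns `property`,
#'   `origin` (one of malt, hops, yeast, wild, other) and `aggregate`
#'   (logical). Defaults to origin "other", no aggregates.
#' @return an object of class `flv_chem`.
#' @export
compound_matrix <- function(beers, values, property_meta = NULL) {
  stopifnot(is.data.frame(beers), is.matrix(values))
  need <- c("beer_id", "style", "abv")
  miss <- setdiff(need, names(beers))
  stop_if(length(miss) > 0, "beers metadata lacks column(s): ",
          paste(miss, collapse = ", "))
  dup <- beers$beer_id[duplicated(beers$beer_id)]
  stop_if(length(dup) > 0, "duplicate beer_id: ",
          paste(unique(dup), collapse = ", "))
  stop_if(nrow(beers) != nrow(values),
          "metadata and value matrix disagree on the number of beers")
  stop_if(anyDuplicated(colnames(values)) > 0, "property names must be unique")
  stop_if(any(is.infinite(values)), "non-finite (infinite) concentration values")
  rownames(values) <- beers$beer_id
  if (is.null(property_meta)) {
    property_meta <- data.frame(property = colnames(values),
                                origin = "other", aggregate = FALSE,
                                stringsAsFactors = FALSE)
  }
  stop_if(!setequal(property_meta$property, colnames(values)),
          "property_meta does not match the value matrix columns")
  property_meta <- property_meta[match(colnames(values), property_meta$property), ]
  rownames(property_meta) <- NULL
  structure(list(beers = beers, values = values, property_meta = property_meta),
            class = "flv_chem")
}

#' @export
print.flv_chem <- function(x, ...) {
  cat(sprintf("<flv_chem> %d beers x %d properties, %d styles\n",
              nrow(x$values), ncol(x$values), length(unique(x$beers$style))))
  agg <- sum(x$property_meta$aggregate)
  if (agg > 0) cat(sprintf("  including %d aggregate properties\n", agg))
  nm <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", nm, 100 * nm / length(x$values)))
  invisible(x)
}

#' Read a chemistry CSV into a compound matrix
#'
#' Expects a header row with `beer_id`, `style`, `abv`, optionally
#' `price_per_l`, followed by one numeric column per chemical property.
#' Empty cells become missing values (never zero).
#'
#' @param path path to a CSV file.
#' @param property_origins optional named character vector mapping property
#'   names to origin classes (malt, hops, yeast, wild, other).
#' @return an object of class [compound_matrix()].
#' @export
load_chemistry <- function(path, property_origins = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("beer_id", "style", "abv")
  miss <- setdiff(need, names(raw))
  stop_if(length(miss) > 0, "chemistry CSV lacks column(s): ",
          paste(miss, collapse = ", "))
  meta_cols <- intersect(c("beer_id", "style", "abv", "price_per_l"), names(raw))
  prop_cols <- setdiff(names(raw), meta_cols)
  stop_if(length(prop_cols) == 0, "chemistry CSV contains no property columns")
  vals <- matrix(NA_real_, nrow(raw), length(prop_cols),
                 dimnames = list(raw$beer_id, prop_cols))
  for (j in seq_along(prop_cols)) {
    col <- raw[[prop_cols[j]]]
    if (is.character(col)) {
      col[!nzchar(trimws(col))] <- NA
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      stop_if(length(bad) > 0,
              sprintf("non-numeric value in column '%s', row %d ('%s')",
                      prop_cols[j], bad[1], col[bad[1]]))
      col <- num
    }
    vals[, j] <- as.numeric(col)
  }
  pm <- data.frame(property = prop_cols, origin = "other", aggregate = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(property_origins)) {
    hit <- intersect(names(property_origins), pm$property)
    pm$origin[match(hit, pm$property)] <- unname(property_origins[hit])
  }
  compound_matrix(raw[meta_cols], vals, pm)
}

#' Write a compound matrix to CSV
#'
#' @param chem a [compound_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chemistry <- function(chem, path) {
  df <- cbind(chem$beers, as.data.frame(chem$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Decide and apply a log transform for one property
#'
#' A property is log-transformed when the Shapiro-Wilk test rejects
#' normality of the raw values (p < `alpha`) while not rejecting it on the
#' log scale, i.e. when the distribution looks log-normal rather than
#' normal. The log uses `log(x + eps)` with `eps` equal to half the
#' smallest positive observed value, so zero concentrations (compounds
#' below detection) stay usable.
#'
#' @param x numeric vector of raw values for one property (may contain NA).
#' @param alpha significance threshold for both Shapiro-Wilk tests.
#' @return list with `flag` (logical), `transformed` (the vector, logged
#'   when flagged), `eps`, and the two p-values `p_raw`, `p_log`.
#' @export
select_log_transform <- function(x, alpha = 0.05) {
  obs <- x[!is.na(x)]
  stop_if(length(obs) < 3, "need at least 3 non-missing values")
  if (length(unique(obs)) == 1) {
    warning("constant property: normality test undefined, no transform")
    return(list(flag = FALSE, transformed = x, eps = 0,
                p_raw = NA_real_, p_log = NA_real_))
  }
  pos <- obs[obs > 0]
  eps <- if (length(pos) > 0) min(pos) / 2 else 0
  if (any(obs + eps <= 0)) {
    warning("non-positive values persist after eps offset, no transform")
    return(list(flag = FALSE, transformed = x, eps = eps,
                p_raw = NA_real_, p_log = NA_real_))
  }
  sw <- function(v) {
    if (length(v) > 4999) v <- v[round(seq(1, length(v), length.out = 4999))]
    if (length(unique(v)) == 1) return(NA_real_)
    shapiro.test(v)$p.value
  }
  p_raw <- sw(obs)
  p_log <- sw(log(obs + eps))
  flag <- isTRUE(p_raw < alpha) && isTRUE(p_log >= alpha)
  out <- x
  if (flag) out <- log(x + eps)
  list(flag = flag, transformed = out, eps = eps, p_raw = p_raw, p_log = p_log)
}

#' Replace missing measurements by per-property means
#'
#' @param chem a [compound_matrix()].
#' @return list with `chem` (imputed copy) and `report`, a data.frame of
#'   per-property missing counts and fill values.
#' @export
impute_missing <- function(chem) {
  vals <- chem$values
  n_miss <- colSums(is.na(vals))
  all_gone <- colnames(vals)[n_miss == nrow(vals)]
  stop_if(length(all_gone) > 0, "property with no observed values: ",
          paste(all_gone, collapse = ", "))
  fills <- colMeans(vals, na.rm = TRUE)
  for (j in which(n_miss > 0)) {
    vals[is.na(vals[, j]), j] <- fills[j]
  }
  out <- chem
  out$values <- vals
  list(chem = out,
       report = data.frame(property = colnames(vals), n_missing = n_miss,
                           fill_value = ifelse(n_miss > 0, fills, NA_real_),
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Append aggregate properties from weighted-sum recipes
#'
#' Several study-level attributes (total esters, total acids, hop aroma,
#' sulfur compounds, caloric value) are weighted sums of individually
#' measured compounds. Recipes give, per aggregate, the component
#' properties and their weights.
#'
#' @param chem a [compound_matrix()].
#' @param recipes named list; each element is a list with `components`
#'   (named numeric vector of weights) and optionally `origin`.
#' @return a [compound_matrix()] with the aggregate columns appended and
#'   flagged.
#' @export
derive_aggregates <- function(chem, recipes) {
  if (length(recipes) == 0) return(chem)
  stop_if(is.null(names(recipes)) || any(!nzchar(names(recipes))),
          "recipes must be a named list")
  vals <- chem$values
  add <- matrix(NA_real_, nrow(vals), length(recipes),
                dimnames = list(rownames(vals), names(recipes)))
  origins <- character(length(recipes))
  for (i in seq_along(recipes)) {
    rc <- recipes[[i]]
    w <- rc$components
    stop_if(is.null(names(w)), "recipe '", names(recipes)[i],
            "' needs a named component weight vector")
    unknown <- setdiff(names(w), colnames(vals))
    stop_if(length(unknown) > 0, "recipe '", names(recipes)[i],
            "' references unknown property: ", paste(unknown, collapse = ", "))
    add[, i] <- as.numeric(vals[, names(w), drop = FALSE] %*% w)
    origins[i] <- rc$origin %||% "other"
  }
  pm <- rbind(chem$property_meta,
              data.frame(property = names(recipes), origin = origins,
                         aggregate = TRUE, stringsAsFactors = FALSE))
  compound_matrix(chem$beers, cbind(vals, add), pm)
}

#' Style-stratified train/test split
#'
#' Allocates `round(n_style * train_frac)` beers of each style to the
#' training set using largest-remainder rounding, so that the global train
#' count equals `round(n * train_frac)` exactly (175/75 for the study's
#' 250-beer style table at 70%).
#'
#' @param chem a [compound_matrix()] or a data.frame with `beer_id`, `style`.
#' @param train_frac fraction of beers assigned to training, in (0, 1).
#' @param seed integer seed controlling which beers within a style land in
#'   which split.
#' @return list with character vectors `train` and `test` of beer ids.
#' @export
split_stratified <- function(chem, train_frac = 0.7, seed = 1) {
  stop_if(!(train_frac > 0 && train_frac < 1), "train_frac must be in (0, 1)")
  beers <- if (inherits(chem, "flv_chem")) chem$beers else chem
  styles <- split(beers$beer_id, beers$style)
  n_s <- vapply(styles, length, integer(1))
  exact <- n_s * train_frac
  base <- floor(exact)
  slots <- round(sum(n_s) * train_frac) - sum(base)
  rem <- exact - base
  ord <- order(-rem, names(styles))
  take <- base
  if (slots > 0) take[ord[seq_len(slots)]] <- take[ord[seq_len(slots)]] + 1
  set.seed(seed)
  train <- character(0)
  for (s in names(styles)) {
    ids <- styles[[s]]
    k <- take[[s]]
    picked <- if (k >= length(ids)) ids else sample(ids, k)
    train <- c(train, picked)
  }
  list(train = sort(train), test = sort(setdiff(beers$beer_id, train)))
}

#' Standardize properties with train-set statistics
#'
#' Fits per-property mean and standard deviation on the training block and
#' applies them to any other block. Constant properties are centered and
#' the scale forced to 1 (with a warning) rather than dividing by zero.
#'
#' @param values numeric matrix (beers x properties).
#' @param state `NULL` to fit a new state, or a state returned by a
#'   previous call, to apply train statistics to new data.
#' @return list with `values` (standardized matrix) and `state`.
#' @export
standardize <- function(values, state = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(state)) {
    mu <- colMeans(values)
    sdv <- apply(values, 2, sd)
    const <- sdv == 0 | !is.finite(sdv)
    if (any(const)) {
      warning("constant property forced to scale 1: ",
              paste(colnames(values)[const], collapse = ", "))
      sdv[const] <- 1
    }
    state <- list(mean = mu, sd = sdv)
  } else {
    stop_if(!setequal(names(state$mean), colnames(values)),
            "property sets of state and data do not match")
    values <- values[, names(state$mean), drop = FALSE]
  }
  out <- sweep(sweep(values, 2, state$mean, "-"), 2, state$sd, "/")
  list(values = out, state = state)
}

#' Fit the full preprocessing state on training beers
#'
#' Chains the study's preprocessing: per-property log-transform selection
#' (Shapiro-Wilk on raw and log values), mean imputation, and
#' standardization -- all statistics fit on the training beers only, so the
#' same state can be applied to test beers or to counterfactual (spiked)
#' rows.
#'
#' @param chem a [compound_matrix()].
#' @param train_ids beer ids forming the training set.
#' @param log_alpha Shapiro-Wilk threshold for the log decision.
#' @return an object of class `flv_transform`.
#' @export
preprocess_fit <- function(chem, train_ids, log_alpha = 0.05) {
  stop_if(!all(train_ids %in% rownames(chem$values)),
          "train_ids contains unknown beers")
  tr <- chem$values[train_ids, , drop = FALSE]
  p <- ncol(tr)
  log_flags <- logical(p); eps <- numeric(p)
  for (j in seq_len(p)) {
    dec <- withCallingHandlers(
      select_log_transform(tr[, j], alpha = log_alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    log_flags[j] <- dec$flag
    eps[j] <- dec$eps
  }
  logged <- tr
  for (j in which(log_flags)) logged[, j] <- log(tr[, j] + eps[j])
  fill <- colMeans(logged, na.rm = TRUE)
  bad <- !is.finite(fill)
  stop_if(any(bad), "property with no observed training values: ",
          paste(colnames(tr)[bad], collapse = ", "))
  for (j in seq_len(p)) logged[is.na(logged[, j]), j] <- fill[j]
  std <- suppressWarnings(standardize(logged))
  structure(list(properties = colnames(tr), log_flags = setNames(log_flags, colnames(tr)),
                 eps = setNames(eps, colnames(tr)),
                 imputed_means = setNames(fill, colnames(tr)),
                 center = std$state$mean, scale = std$state$sd),
            class = "flv_transform")
}

#' Apply a fitted preprocessing state to raw concentration rows
#'
#' @param state an `flv_transform` from [preprocess_fit()].
#' @param values raw value matrix (or a [compound_matrix()]); columns must
#'   match the properties the state was fit on.
#' @return standardized numeric matrix in model feature space.
#' @export
preprocess_apply <- function(state, values) {
  if (inherits(values, "flv_chem")) values <- values$values
  if (is.null(dim(values))) values <- matrix(values, nrow = 1,
                                             dimnames = list(NULL, names(values)))
  stop_if(!all(state$properties %in% colnames(values)),
          "data lacks properties the preprocessing state was fit on")
  values <- values[, state$properties, drop = FALSE]
  for (j in which(state$log_flags)) {
    values[, j] <- log(values[, j] + state$eps[j])
  }
  for (j in seq_along(state$properties)) {
    values[is.na(values[, j]), j] <- state$imputed_means[j]
  }
  sweep(sweep(values, 2, state$center, "-"), 2, state$scale, "/")
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations (midrank tie handling,
#' pairwise-complete observations) between the columns of `A`, or between
#' columns of `A` and `B` when `B` is given (rectangular
#' cross-correlation). Two-sided p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param A numeric matrix or data.frame.
#' @param B optional second matrix sharing rows with `A`.
#' @return an object of class `flv_corr` with elements `rho`, `p`, `n`.
#' @export
spearman_matrix <- function(A, B = NULL) {
  A <- as.matrix(A)
  square <- is.null(B)
  B <- if (square) A else as.matrix(B)
  stop_if(nrow(A) != nrow(B), "A and B must share rows (observations)")
  pair_n <- crossprod(!is.na(A) + 0, !is.na(B) + 0)
  if (any(pair_n < 3)) {
    warning("pairs with fewer than 3 complete observations: rho set to NA")
  }
  complete <- !anyNA(A) && !anyNA(B)
  if (complete) {
    ra <- apply(A, 2, rank)
    rb <- if (square) ra else apply(B, 2, rank)
    rho <- suppressWarnings(cor(ra, rb))
  } else {
    rho <- suppressWarnings(cor(A, B, method = "spearman",
                                use = "pairwise.complete.obs"))
  }
  rho[pair_n < 3] <- NA_real_
  tstat <- rho * sqrt(pmax(pair_n - 2, 0) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = pmax(pair_n - 2, 1))
  p[!is.finite(rho)] <- NA_real_
  p[is.finite(rho) & abs(rho) == 1] <- 0
  if (square) {
    diag(rho) <- 1
    diag(p) <- 0
  }
  structure(list(rho = rho, p = p, n = pair_n, square = square),
            class = "flv_corr")
}

#' @export
print.flv_corr <- function(x, ...) {
  cat(sprintf("<flv_corr> %d x %d Spearman correlations\n",
              nrow(x$rho), ncol(x$rho)))
  invisible(x)
}

#' Flatten a correlation object to long format
#'
#' @param corr an `flv_corr` from [spearman_matrix()].
#' @param upper_only for square matrices, keep each unordered pair once.
#' @return data.frame with columns `prop_a`, `prop_b`, `rho`, `p`, `n`.
#' @export
corr_long <- function(corr, upper_only = TRUE) {
  rn <- rownames(corr$rho); cn <- colnames(corr$rho)
  out <- expand.grid(prop_a = rn, prop_b = cn, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$rho <- as.vector(corr$rho)
  out$p <- as.vector(corr$p)
  out$n <- as.vector(corr$n)
  if (isTRUE(corr$square) && upper_only) {
    keep <- match(out$prop_a, rn) < match(out$prop_b, cn)
    out <- out[keep, ]
  }
  rownames(out) <- NULL
  out
}
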