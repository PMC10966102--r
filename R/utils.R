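`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of determination
#'
#' R-squared of predictions against observations, `1 - SSE/SST`, with SST
#' taken about the mean of the observed values in the evaluated set. Can be
#' negative when the predictions do worse than the observed mean.
#'
#' @param obs numeric vector of observed values.
#' @param pred numeric vector of predictions, same length.
#' @return a single numeric value.
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  keep <- is.finite(obs) & is.finite(pred)
  obs <- obs[keep]; pred <- pred[keep]
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("r_squared undefined: observed values are constant")
  1 - sum((obs - pred)^2) / sst
}

# deterministic fan-out of one user seed into per-stage seeds (< 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(chemistry = 11L, panel = 23L, reviews = 37L, split = 53L,
               bench = 67L, dissect = 79L, spike = 97L, pipeline = 101L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(as.character(stage)))
  as.integer((as.numeric(seed) %% 1000003) * 1009 + off)
}

# midranks, decreasing = rank 1 for the largest |value|
rank_desc <- function(x) rank(-x, ties.method = "average")

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
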