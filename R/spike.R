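#' Ethanol-normalized concentration
#'
#' Divides a concentration by the beer's ABV so that style-typical targets
#' scale with beer strength ("per % ABV" units). Beers below `abv_floor`
#' (including 0.0% beers) are normalized against the floor instead, and
#' flagged.
#'
#' @param conc concentration (mg/L), vectorized.
#' @param abv alcohol by volume, % v/v (scalar or same length).
#' @param abv_floor minimum ABV used as denominator.
#' @return numeric vector with attribute `floored` (logical).
#' @export
ethanol_normalize <- function(conc, abv, abv_floor = 0.5) {
  stop_if(any(abv < 0), "negative ABV")
  denom <- pmax(abv, abv_floor)
  out <- conc / denom
  attr(out, "floored") <- abv < abv_floor
  out
}

#' Within-style spiking targets
#'
#' The target for each compound is a statistic (95th percentile by
#' default, or the mean) of the ethanol-normalized concentrations across
#' the beers of one style. Percentiles interpolate linearly between order
#' statistics.
#'
#' @param chem a [compound_matrix()].
#' @param style style label defining the reference group.
#' @param compounds compound names to target.
#' @param statistic "p95" or "mean".
#' @param abv_floor passed to [ethanol_normalize()].
#' @return named numeric vector of targets in normalized units
#'   (mg/L per % ABV), with the statistic recorded as an attribute.
#' @export
style_targets <- function(chem, style, compounds,
                          statistic = c("p95", "mean"), abv_floor = 0.5) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(chem, "flv_chem"))
  idx <- chem$beers$style == style
  stop_if(!any(idx), "unknown style: ", style)
  stop_if(sum(idx) < 3, "style '", style, "' has fewer than 3 beers")
  unknown <- setdiff(compounds, colnames(chem$values))
  stop_if(length(unknown) > 0, "unknown compound: ",
          paste(unknown, collapse = ", "))
  abv <- chem$beers$abv[idx]
  out <- vapply(compounds, function(cc) {
    norm <- ethanol_normalize(chem$values[idx, cc], abv, abv_floor)
    if (statistic == "p95") {
      as.numeric(quantile(norm, 0.95, type = 7, na.rm = TRUE))
    } else {
      mean(norm, na.rm = TRUE)
    }
  }, numeric(1))
  attr(out, "statistic") <- statistic
  attr(out, "style") <- style
  out
}

#' Build a non-negative spiking plan for a base beer
#'
#' Converts normalized style targets back to concentrations at the
#' reference ABV and computes the additions needed to reach them.
#' Additions are never negative -- compounds already above target are left
#' alone -- and compounds on the exclusion list (e.g. ethanol, for
#' alcohol-free variants) are dropped from the plan.
#'
#' @param chem a [compound_matrix()].
#' @param base_beer_id beer to spike.
#' @param targets named vector from [style_targets()].
#' @param exclude compounds to leave out of the plan.
#' @param abv_floor floor used when denormalizing against the base beer's
#'   ABV.
#' @return an object of class `flv_spike_plan` (a data.frame with columns
#'   `compound`, `current`, `target`, `addition`, plus metadata
#'   attributes).
#' @export
spiking_plan <- function(chem, base_beer_id, targets, exclude = character(0),
                         abv_floor = 0.5) {
  stopifnot(inherits(chem, "flv_chem"))
  stop_if(!base_beer_id %in% rownames(chem$values),
          "unknown base beer: ", base_beer_id)
  keep <- setdiff(names(targets), exclude)
  targets <- targets[keep]
  missing <- keep[is.na(chem$values[base_beer_id, keep])]
  stop_if(length(missing) > 0, "base beer lacks a measured concentration for: ",
          paste(missing, collapse = ", "))
  abv_ref <- max(chem$beers$abv[chem$beers$beer_id == base_beer_id], abv_floor)
  current <- chem$values[base_beer_id, keep]
  target_conc <- unname(targets) * abv_ref
  addition <- pmax(0, target_conc - current)
  plan <- data.frame(compound = keep, current = unname(current),
                     target = target_conc, addition = unname(addition),
                     stringsAsFactors = FALSE)
  structure(plan, class = c("flv_spike_plan", "data.frame"),
            base_beer_id = base_beer_id, abv_ref = abv_ref,
            statistic = attr(targets, "statistic") %||% "unknown",
            style = attr(targets, "style") %||% NA_character_)
}

#' @export
print.flv_spike_plan <- function(x, ...) {
  cat(sprintf("<flv_spike_plan> base %s, style %s, statistic %s (ref ABV %.2f)\n",
              attr(x, "base_beer_id"), attr(x, "style"),
              attr(x, "statistic"), attr(x, "abv_ref")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Predicted appreciation uplift of a spiking plan
#'
#' Applies a plan's additions to the base beer's raw concentrations,
#' pushes both rows through the training preprocessing state (log
#' transforms, imputation, standardization), and reports the difference in
#' model prediction -- the counterfactual appreciation gain the model
#' expects from the spike.
#'
#' @param model a fitted appreciation model (`flv_model`).
#' @param chem a [compound_matrix()].
#' @param plan an `flv_spike_plan`.
#' @param state the `flv_transform` fit on the model's training beers.
#' @return list with `delta`, `pred_base`, `pred_spiked`.
#' @export
predict_uplift <- function(model, chem, plan, state) {
  stopifnot(inherits(plan, "flv_spike_plan"), inherits(state, "flv_transform"))
  base_id <- attr(plan, "base_beer_id")
  base_row <- chem$values[base_id, , drop = FALSE]
  unknown <- setdiff(plan$compound, colnames(base_row))
  stop_if(length(unknown) > 0, "plan compounds missing from the feature space: ",
          paste(unknown, collapse = ", "))
  spiked <- base_row
  spiked[, plan$compound] <- spiked[, plan$compound] + plan$addition
  Xb <- preprocess_apply(state, base_row)
  Xs <- preprocess_apply(state, spiked)
  pb <- as.numeric(predict(model, Xb))
  ps <- as.numeric(predict(model, Xs))
  list(delta = ps - pb, pred_base = pb, pred_spiked = ps)
}

#' Exact two-sided binomial test for a directional difference test
#'
#' In a paired tasting, each of `n` assessors picks the sample they find
#' more intense (or prefer); under the null both samples are picked with
#' probability 1/2. The exact two-sided p-value sums the tail
#' probabilities not exceeding P(k), capped at 1 -- appropriate at panel
#' sizes like n = 20 or 13 where normal approximations are not.
#'
#' @param k number of assessors choosing the spiked sample.
#' @param n number of assessors.
#' @return list with `p_value`, `k`, `n`, `proportion`.
#' @export
directional_binomial <- function(k, n) {
  stop_if(n < 1 || k < 0 || k > n, "need 0 <= k <= n, n >= 1")
  p <- binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  list(p_value = min(p, 1), k = as.integer(k), n = as.integer(n),
       proportion = k / n)
}

#' Tabulate tasting outcomes with exact binomial p-values
#'
#' @param counts data.frame with columns `attribute`, `k` (choosing the
#'   spiked sample) and `n`.
#' @param alpha significance threshold for the `significant` flag.
#' @return data.frame with `p_value` and `significant` appended.
#' @export
tasting_outcomes <- function(counts, alpha = 0.05) {
  need <- c("attribute", "k", "n")
  stop_if(!all(need %in% names(counts)),
          "counts needs columns attribute, k, n")
  counts$p_value <- vapply(seq_len(nrow(counts)), function(i)
    directional_binomial(counts$k[i], counts$n[i])$p_value, numeric(1))
  counts$significant <- counts$p_value < alpha
  counts
}
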