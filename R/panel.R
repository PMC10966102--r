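#' Trained-panel score container
#'
#' Long-format quantitative descriptive analysis records: one row per
#' (beer, taster, session, attribute) with an intensity score on the
#' panel's 7-point scale.
#'
#' @param records data.frame with columns `beer_id`, `taster_id`,
#'   `session_id`, `attribute`, `score`.
#' @param normalized whether scores are already per-taster z-scores.
#' @return an object of class `flv_panel` (a data.frame).
#' @export
panel_scores <- function(records, normalized = FALSE) {
  need <- c("beer_id", "taster_id", "session_id", "attribute", "score")
  miss <- setdiff(need, names(records))
  stop_if(length(miss) > 0, "panel records lack column(s): ",
          paste(miss, collapse = ", "))
  stop_if(!is.numeric(records$score), "scores must be numeric")
  if (!normalized) {
    bad <- records$score < 1 | records$score > 7
    stop_if(any(bad, na.rm = TRUE), "raw scores must lie on the 7-point scale (1-7)")
  }
  key <- do.call(paste, c(records[c("beer_id", "taster_id", "session_id",
                                    "attribute")], sep = "\r"))
  stop_if(anyDuplicated(key) > 0,
          "duplicate (beer, taster, session, attribute) record")
  structure(as.data.frame(records), class = c("flv_panel", "data.frame"),
            normalized = normalized)
}

#' Per-taster z-score normalization
#'
#' Each taster's scores are centered by that taster's grand mean over all
#' their ratings and scaled by their sample (n-1) standard deviation,
#' removing individual scale-use differences. A taster with zero variance
#' contributes centered values of 0 (with a warning).
#'
#' @param scores an `flv_panel` of raw scores.
#' @return an `flv_panel` with normalized scores.
#' @export
taster_zscore <- function(scores) {
  stopifnot(inherits(scores, "flv_panel"))
  out <- scores
  for (t in unique(scores$taster_id)) {
    idx <- scores$taster_id == t
    v <- scores$score[idx]
    stop_if(length(v) < 2, "taster '", t, "' has fewer than 2 ratings")
    s <- sd(v)
    if (s == 0) {
      warning("taster '", t, "' gave constant scores; normalized values set to 0")
      out$score[idx] <- 0
    } else {
      out$score[idx] <- (v - mean(v)) / s
    }
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Aggregate normalized scores to beer-level sensory profiles
#'
#' Cell values are means over all available (taster, session) ratings;
#' absent panelists simply reduce the per-cell n, no imputation happens.
#'
#' @param scores an `flv_panel` of normalized scores.
#' @return an object of class `flv_profile`: list with `values`
#'   (beers x attributes matrix of mean z-scores) and `n` (ratings per cell).
#' @export
beer_attribute_means <- function(scores) {
  stopifnot(inherits(scores, "flv_panel"))
  stop_if(!isTRUE(attr(scores, "normalized")),
          "scores must be normalized first (taster_zscore)")
  beers <- sort(unique(scores$beer_id))
  attrs <- sort(unique(scores$attribute))
  fb <- factor(scores$beer_id, levels = beers)
  fa <- factor(scores$attribute, levels = attrs)
  sums <- tapply(scores$score, list(fb, fa), sum)
  n <- tapply(scores$score, list(fb, fa), length)
  n[is.na(n)] <- 0
  vals <- sums / ifelse(n == 0, NA, n)
  if (any(n == 0)) {
    warning(sum(n == 0), " beer x attribute cell(s) have no ratings")
  }
  structure(list(values = vals, n = n), class = "flv_profile")
}

#' @export
print.flv_profile <- function(x, ...) {
  cat(sprintf("<flv_profile> %d beers x %d attributes (mean z-scores)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Panel consistency by repeated-sample ANOVA
#'
#' For each repeated beer and attribute, a one-way ANOVA tests whether the
#' session explains score differences. Consistency is reported as the
#' fraction of tests with p > `alpha` (no detectable session effect). Cells
#' with zero variance everywhere leave the F test undefined and are counted
#' as consistent, flagged in the table.
#'
#' @param scores an `flv_panel` (raw or normalized).
#' @param repeated_ids beers that were served in more than one session.
#' @param alpha significance level.
#' @return list with `fraction` (consistent share) and `table`
#'   (per beer x attribute p-values).
#' @export
panel_consistency <- function(scores, repeated_ids, alpha = 0.05) {
  stopifnot(inherits(scores, "flv_panel"))
  rows <- list()
  for (b in repeated_ids) {
    sub_b <- scores[scores$beer_id == b, ]
    stop_if(length(unique(sub_b$session_id)) < 2,
            "repeated beer '", b, "' has fewer than 2 sessions")
    for (a in unique(sub_b$attribute)) {
      sub <- sub_b[sub_b$attribute == a, ]
      if (length(unique(sub$session_id)) < 2 || nrow(sub) < 3) next
      if (var(sub$score) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          beer_id = b, attribute = a, p = NA_real_, consistent = TRUE,
          degenerate = TRUE, stringsAsFactors = FALSE)
        next
      }
      fit <- aov(score ~ factor(session_id), data = sub)
      tab <- summary(fit)[[1]]
      p <- tab[["Pr(>F)"]][1]
      degen <- !is.finite(p)
      rows[[length(rows) + 1]] <- data.frame(
        beer_id = b, attribute = a, p = p,
        consistent = if (degen) TRUE else p > alpha,
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  stop_if(is.null(tab), "no testable repeated beer x attribute cells")
  list(fraction = mean(tab$consistent), table = tab)
}
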