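#' Consumer review container
#'
#' One row per review: the five numeric sub-scores used by the public
#' review platform (appearance, aroma, taste, palate, overall), an optional
#' free text, and the labels assigned by two independent language
#' detectors.
#'
#' @param records data.frame with columns `beer_id`, `rater_id`,
#'   `appearance`, `aroma`, `taste`, `palate`, `overall`, `text`, `lang1`,
#'   `lang2`.
#' @return an object of class `flv_reviews` (a data.frame).
#' @export
review_set <- function(records) {
  need <- c("beer_id", "rater_id", "appearance", "aroma", "taste", "palate",
            "overall", "text", "lang1", "lang2")
  miss <- setdiff(need, names(records))
  stop_if(length(miss) > 0, "review records lack column(s): ",
          paste(miss, collapse = ", "))
  stop_if(any(!nzchar(records$rater_id)), "rater_id must be non-empty")
  for (sc in c("appearance", "aroma", "taste", "palate", "overall")) {
    stop_if(!is.numeric(records[[sc]]), "sub-score '", sc, "' must be numeric")
  }
  structure(as.data.frame(records), class = c("flv_reviews", "data.frame"))
}

#' Read / write reviews as JSON lines
#'
#' @param path path to a `.jsonl` file (one JSON object per line).
#' @return for the reader, an [review_set()]; the writer returns `path`.
#' @export
read_reviews_jsonl <- function(path) {
  review_set(jsonlite::stream_in(file(path), verbose = FALSE))
}

#' @rdname read_reviews_jsonl
#' @param reviews an [review_set()].
#' @export
write_reviews_jsonl <- function(reviews, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(reviews), con, verbose = FALSE)
  invisible(path)
}

#' Filter reviews by language consensus and rater activity
#'
#' A review is kept iff both language detectors call it English and its
#' rater has at least `min_reviews` English-consensus reviews in the
#' corpus. Counting activity on the language-filtered corpus makes the
#' operation idempotent and order-independent.
#'
#' @param reviews an [review_set()].
#' @param min_reviews minimum per-rater review count (the study used 100).
#' @return list with `reviews` (filtered set) and `report` (counts removed
#'   per rule).
#' @export
filter_reviews <- function(reviews, min_reviews = 100) {
  stopifnot(inherits(reviews, "flv_reviews"))
  if (nrow(reviews) == 0) {
    return(list(reviews = reviews,
                report = data.frame(rule = c("language", "low_activity"),
                                    removed = c(0L, 0L))))
  }
  english <- reviews$lang1 == "en" & reviews$lang2 == "en"
  en_set <- reviews[english, , drop = FALSE]
  counts <- table(en_set$rater_id)
  active <- names(counts)[counts >= min_reviews]
  keep <- en_set$rater_id %in% active
  out <- en_set[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reviews = structure(out, class = class(reviews)),
       report = data.frame(rule = c("language", "low_activity"),
                           removed = c(sum(!english), sum(!keep))))
}

#' Per-rater standardization and per-beer mean scores
#'
#' Each sub-score is centered by the rater's mean and scaled by the
#' rater's sample standard deviation, removing rater bias and scale-use
#' differences; the standardized scores are then averaged per beer.
#' Single-review raters (or zero-variance raters) contribute 0 after
#' centering, with a warning.
#'
#' @param reviews a filtered [review_set()].
#' @return data.frame with one row per beer: mean standardized sub-scores
#'   and the review count.
#' @export
rater_center_scores <- function(reviews) {
  stopifnot(inherits(reviews, "flv_reviews"))
  subs <- c("appearance", "aroma", "taste", "palate", "overall")
  df <- as.data.frame(reviews)
  degenerate <- character(0)
  for (r in unique(df$rater_id)) {
    idx <- df$rater_id == r
    for (sc in subs) {
      v <- df[[sc]][idx]
      s <- if (length(v) > 1) sd(v) else 0
      if (!is.finite(s) || s == 0) {
        df[[sc]][idx] <- 0
        degenerate <- union(degenerate, r)
      } else {
        df[[sc]][idx] <- (v - mean(v)) / s
      }
    }
  }
  if (length(degenerate) > 0) {
    warning(length(degenerate),
            " rater(s) with a single review or zero variance contribute 0")
  }
  agg <- aggregate(df[subs], by = list(beer_id = df$beer_id), FUN = mean)
  agg$n_reviews <- as.integer(table(df$beer_id)[agg$beer_id])
  agg[order(agg$beer_id), , drop = FALSE]
}

#' Sensory lexicon
#'
#' Holds the resources used by text normalization and enrichment: a slang
#' and misspelling map, protected beer-context terms kept verbatim
#' (e.g. 'Chimay', 'Lambic'), synonym groups collapsed to one canonical
#' term ('floral'/'flower'/'flowery'), and the sensory vocabulary with its
#' mapping to panel attributes.
#'
#' @param slang_map named character vector (variant -> replacement).
#' @param protected_terms character vector, never rewritten.
#' @param synonym_groups named list: canonical term -> character vector of
#'   variants.
#' @param sensory_vocab named character vector: canonical sensory term ->
#'   panel attribute it tracks.
#' @return an object of class `flv_lexicon`.
#' @export
lexicon <- function(slang_map = character(0), protected_terms = character(0),
                    synonym_groups = list(), sensory_vocab = character(0)) {
  stop_if(anyDuplicated(names(synonym_groups)) > 0,
          "canonical synonym terms must be unique")
  structure(list(slang_map = slang_map,
                 protected_terms = protected_terms,
                 synonym_groups = synonym_groups,
                 sensory_vocab = sensory_vocab),
            class = "flv_lexicon")
}

#' Built-in illustrative lexicon
#'
#' The study's slang dictionary and sensory vocabulary are unpublished;
#' this default covers the vocabulary used by the synthetic review
#' generator and is meant to be replaced (see [read_lexicon()]) for real
#' corpora.
#'
#' @return an `flv_lexicon`.
#' @export
default_lexicon <- function() {
  lexicon(
    slang_map = c(gr8 = "great", luv = "love", hoppyy = "hoppy",
                  sweeet = "sweet", delish = "delicious", bier = "beer"),
    protected_terms = c("Chimay", "Lambic", "Tripel", "Gueuze", "Saison"),
    synonym_groups = list(
      floral = c("flower", "flowery", "florals"),
      fruity = c("fruit", "fruits", "fruitiness"),
      hoppy = c("hop", "hops", "hoppiness"),
      malty = c("malt", "malts", "maltiness"),
      sour = c("sourness", "tart", "tartness", "acidic", "acid", "acidity"),
      sweet = c("sweetness", "sugary"),
      bitter = c("bitterness", "bitterish"),
      banana = c("bananas", "isoamyl"),
      alcoholic = c("alcohol", "boozy", "booze"),
      full = c("fullness", "thick", "body")
    ),
    sensory_vocab = c(hoppy = "hop_aroma", bitter = "bitter", sweet = "sweet",
                      sour = "sour", malty = "malt_taste",
                      fruity = "ester_aroma", banana = "banana_ester",
                      floral = "floral_aroma", alcoholic = "alcohol",
                      full = "body")
  )
}

#' Read a lexicon from YAML
#'
#' @param path YAML file with keys `slang_map`, `protected_terms`,
#'   `synonym_groups`, `sensory_vocab`.
#' @return an `flv_lexicon`.
#' @export
read_lexicon <- function(path) {
  y <- yaml::read_yaml(path)
  lexicon(slang_map = unlist(y$slang_map %||% list()),
          protected_terms = unlist(y$protected_terms %||% character(0)),
          synonym_groups = y$synonym_groups %||% list(),
          sensory_vocab = unlist(y$sensory_vocab %||% list()))
}

# minimal rule-based lemmatizer/stemmer: plural and inflection suffixes,
# then noun-forming suffixes; protected terms never reach this point
.stem_token <- function(tok) {
  n <- nchar(tok)
  if (n > 4 && grepl("ies$", tok)) tok <- sub("ies$", "y", tok)
  else if (n > 4 && grepl("(sses|shes|ches|xes)$", tok)) tok <- sub("es$", "", tok)
  else if (n > 3 && grepl("s$", tok) && !grepl("ss$", tok)) tok <- sub("s$", "", tok)
  n <- nchar(tok)
  if (n > 5 && grepl("ing$", tok)) tok <- sub("ing$", "", tok)
  else if (n > 4 && grepl("ed$", tok)) tok <- sub("ed$", "", tok)
  n <- nchar(tok)
  if (n > 5 && grepl("ity$", tok)) tok <- sub("ity$", "", tok)
  tok
}

#' Normalize a review text to canonical tokens
#'
#' Pipeline: lowercase, protect the lexicon's beer-context terms, apply the
#' slang map, tokenize, drop numbers and punctuation, collapse synonym
#' groups to their canonical term, then lemmatize/stem remaining tokens.
#' Protected terms pass through unchanged (original casing).
#'
#' @param text a character string (length 1).
#' @param lex an `flv_lexicon`.
#' @return character vector of tokens (possibly empty).
#' @export
normalize_text <- function(text, lex = default_lexicon()) {
  stopifnot(inherits(lex, "flv_lexicon"))
  if (is.na(text) || !nzchar(text)) return(character(0))
  s <- tolower(text)
  # shield protected terms behind placeholders so no later step rewrites them
  shields <- character(0)
  for (i in seq_along(lex$protected_terms)) {
    pt <- lex$protected_terms[i]
    ph <- sprintf("zqprotectedz%dz", i)
    s <- gsub(tolower(pt), ph, s, fixed = TRUE)
    shields[ph] <- pt
  }
  toks <- strsplit(s, "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  slang <- lex$slang_map
  hit <- toks %in% names(slang)
  toks[hit] <- unname(slang[toks[hit]])
  # drop pure numbers and number-bearing fragments such as '75cl'
  toks <- toks[!grepl("[0-9]", toks) | toks %in% names(shields)]
  syn <- lex$synonym_groups
  if (length(syn) > 0) {
    map <- setNames(rep(names(syn), lengths(syn)), unlist(syn))
    hit <- toks %in% names(map)
    toks[hit] <- unname(map[toks[hit]])
  }
  out <- character(length(toks))
  for (i in seq_along(toks)) {
    if (toks[i] %in% names(shields)) {
      out[i] <- shields[[toks[i]]]
    } else if (toks[i] %in% names(syn)) {
      out[i] <- toks[i]            # canonical terms stay as-is
    } else {
      out[i] <- .stem_token(toks[i])
    }
  }
  out
}

#' Split review texts into sentences
#'
#' @param reviews an [review_set()].
#' @return data.frame with `beer_id`, `review` (row index in the set) and
#'   `sentence`.
#' @export
split_sentences <- function(reviews) {
  stopifnot(inherits(reviews, "flv_reviews"))
  txt <- reviews$text
  pieces <- strsplit(ifelse(is.na(txt), "", txt), "(?<=[.!?])\\s+", perl = TRUE)
  n <- lengths(pieces)
  out <- data.frame(beer_id = rep(reviews$beer_id, n),
                    review = rep(seq_len(nrow(reviews)), n),
                    sentence = unlist(pieces), stringsAsFactors = FALSE)
  out <- out[nzchar(trimws(out$sentence)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.sentence_dtm <- function(sentences, lex, vocab = NULL) {
  toks <- lapply(sentences, normalize_text, lex = lex)
  if (is.null(vocab)) vocab <- sort(unique(unlist(toks)))
  ij <- lapply(seq_along(toks), function(i) {
    t <- toks[[i]][toks[[i]] %in% vocab]
    if (length(t) == 0) return(NULL)
    tb <- table(t)
    cbind(i = i, j = match(names(tb), vocab), x = as.numeric(tb))
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij)) ij <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("i", "j", "x")))
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3],
                       dims = c(length(toks), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Train a sentence aspect classifier
#'
#' A regularized multinomial logistic model on bag-of-words counts of
#' normalized tokens, mapping each sentence to one of the six beer aspects
#' (appearance, aroma, taste, palate, overall, irrelevant). Sentences with
#' entirely unseen vocabulary fall back to the intercept (class prior)
#' instead of failing.
#'
#' @param sentences character vector of training sentences.
#' @param labels aspect label per sentence.
#' @param lex an `flv_lexicon` used for token normalization.
#' @param lambda ridge-ish penalty passed to glmnet (small, for stability).
#' @return an object of class `flv_aspect_clf`.
#' @export
train_aspect_classifier <- function(sentences, labels, lex = default_lexicon(),
                                    lambda = 0.01) {
  aspects <- c("appearance", "aroma", "taste", "palate", "overall", "irrelevant")
  stop_if(!all(labels %in% aspects), "labels must be one of: ",
          paste(aspects, collapse = ", "))
  present <- intersect(aspects, unique(labels))
  stop_if(length(present) < 2, "training data must contain at least 2 classes")
  dtm <- .sentence_dtm(sentences, lex)
  stop_if(ncol(dtm) < 2, "training sentences yield fewer than 2 tokens")
  y <- factor(labels, levels = present)
  fit <- glmnet::glmnet(dtm, y, family = "multinomial", alpha = 0,
                        lambda = c(5 * lambda, lambda), standardize = FALSE)
  structure(list(fit = fit, vocab = colnames(dtm), levels = present,
                 lex = lex, lambda = lambda),
            class = "flv_aspect_clf")
}

#' @rdname train_aspect_classifier
#' @param clf a trained `flv_aspect_clf`.
#' @param new_sentences character vector to classify.
#' @return `classify_sentences()` returns a character vector of aspect
#'   labels.
#' @export
classify_sentences <- function(clf, new_sentences) {
  stopifnot(inherits(clf, "flv_aspect_clf"))
  dtm <- .sentence_dtm(new_sentences, clf$lex, vocab = clf$vocab)
  pred <- predict(clf$fit, dtm, s = clf$lambda, type = "class")
  if (is.matrix(pred)) pred <- pred[, 1]
  as.character(pred)
}

#' TFIDF sensory-term enrichment per beer
#'
#' Concatenates each beer's sentences from the kept aspects into one
#' document and scores the lexicon's sensory terms with
#' `tf * (ln((1 + N)/(1 + df)) + 1)` (term frequency times smoothed inverse
#' document frequency). Terms absent from every document get no column;
#' beers without kept sentences keep a zero row and are flagged.
#'
#' @param classified data.frame with columns `beer_id`, `sentence`,
#'   `aspect` (see [split_sentences()] and [classify_sentences()]).
#' @param lex an `flv_lexicon`; scoring is restricted to its
#'   `sensory_vocab`.
#' @param aspects_kept aspects whose sentences form the documents.
#' @return matrix (beers x sensory terms) of enrichment scores with
#'   attribute `empty_beers`.
#' @export
tfidf_enrichment <- function(classified, lex = default_lexicon(),
                             aspects_kept = c("aroma", "taste")) {
  need <- c("beer_id", "sentence", "aspect")
  stop_if(!all(need %in% names(classified)),
          "classified sentences need columns beer_id, sentence, aspect")
  beers <- sort(unique(classified$beer_id))
  kept <- classified[classified$aspect %in% aspects_kept, , drop = FALSE]
  docs <- lapply(split(kept$sentence, factor(kept$beer_id, levels = beers)),
                 function(ss) unlist(lapply(ss, normalize_text, lex = lex)))
  doc_len <- vapply(docs, length, integer(1))
  vocab <- names(lex$sensory_vocab)
  counts <- t(vapply(docs, function(d) {
    vapply(vocab, function(term) sum(d == term), numeric(1))
  }, numeric(length(vocab))))
  present <- colSums(counts) > 0
  counts <- counts[, present, drop = FALSE]
  n_docs <- sum(doc_len > 0)
  df <- colSums(counts > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  tf <- counts / ifelse(doc_len == 0, 1, doc_len)
  scores <- sweep(tf, 2, idf, "*")
  rownames(scores) <- beers
  attr(scores, "empty_beers") <- beers[doc_len == 0]
  if (length(attr(scores, "empty_beers")) > 0) {
    warning(length(attr(scores, "empty_beers")),
            " beer(s) have no kept sentences; zero rows flagged")
  }
  scores
}

#' Agreement between review-derived values and panel profiles
#'
#' Spearman correlation (with two-sided p) between matched columns of a
#' per-beer review-derived table (TFIDF enrichment or centered mean
#' scores) and the trained-panel sensory profile, on shared beers.
#'
#' @param x matrix or data.frame with beer ids as rownames (or a `beer_id`
#'   column).
#' @param profile an `flv_profile` from [beer_attribute_means()].
#' @param mapping named character vector: names are columns of `x`, values
#'   the matched panel attributes.
#' @return data.frame with one row per mapped pair: `review_var`,
#'   `attribute`, `rho`, `p`, `n`.
#' @export
review_panel_agreement <- function(x, profile, mapping) {
  stopifnot(inherits(profile, "flv_profile"))
  if (is.data.frame(x) && "beer_id" %in% names(x)) {
    rownames(x) <- x$beer_id
    x <- x[, setdiff(names(x), "beer_id"), drop = FALSE]
  }
  x <- as.matrix(x)
  shared <- intersect(rownames(x), rownames(profile$values))
  stop_if(length(shared) < 3, "need at least 3 shared beers")
  mapping <- mapping[names(mapping) %in% colnames(x) &
                       mapping %in% colnames(profile$values)]
  stop_if(length(mapping) == 0, "no mapped attribute pairs available")
  A <- x[shared, names(mapping), drop = FALSE]
  B <- profile$values[shared, unname(mapping), drop = FALSE]
  out <- data.frame(review_var = names(mapping), attribute = unname(mapping),
                    rho = NA_real_, p = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mapping)) {
    cc <- spearman_matrix(A[, i, drop = FALSE], B[, i, drop = FALSE])
    out$rho[i] <- cc$rho[1, 1]
    out$p[i] <- cc$p[1, 1]
    out$n[i] <- cc$n[1, 1]
  }
  out
}
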