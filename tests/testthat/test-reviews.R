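mk_reviews <- function(n, rater = "r1", beer = "b1", text = NA_character_,
                       lang1 = "en", lang2 = "en", overall = 5) {
  df <- data.frame(
    beer_id = beer, rater_id = rater, appearance = 5, aroma = 5, taste = 5,
    palate = 5, overall = overall, text = text, lang1 = lang1, lang2 = lang2,
    stringsAsFactors = FALSE)
  review_set(df[rep_len(seq_len(nrow(df)), n), , drop = FALSE])
}

test_that("filtering needs detector consensus and rater activity", {
  both <- rbind(mk_reviews(1, lang1 = "en", lang2 = "fr"),
                mk_reviews(100, rater = "busy"),
                mk_reviews(99, rater = "quiet"))
  out <- filter_reviews(both, min_reviews = 100)
  expect_equal(nrow(out$reviews), 100)
  expect_true(all(out$reviews$rater_id == "busy"))
  expect_equal(out$report$removed, c(1L, 99L))

  at_boundary <- filter_reviews(mk_reviews(100, rater = "exact"), 100)
  expect_equal(nrow(at_boundary$reviews), 100)

  empty <- filter_reviews(mk_reviews(0), 100)
  expect_equal(nrow(empty$reviews), 0)
  expect_equal(empty$report$removed, c(0L, 0L))
})

test_that("filtering is idempotent and order-independent", {
  b <- study_bundle()
  once <- filter_reviews(b$reviews, min_reviews = 50)
  twice <- filter_reviews(once$reviews, min_reviews = 50)
  expect_equal(as.data.frame(twice$reviews), as.data.frame(once$reviews))
  shuffled <- b$reviews[rev(seq_len(nrow(b$reviews))), ]
  class(shuffled) <- class(b$reviews)
  resh <- filter_reviews(shuffled, min_reviews = 50)
  expect_setequal(
    do.call(paste, as.data.frame(resh$reviews)[c("beer_id", "rater_id", "overall")]),
    do.call(paste, as.data.frame(once$reviews)[c("beer_id", "rater_id", "overall")]))
})

test_that("rater centering removes bias and scale before beer means", {
  df <- review_set(data.frame(
    beer_id = c("b1", "b2"), rater_id = "r1",
    appearance = c(10, 20), aroma = c(10, 20), taste = c(10, 20),
    palate = c(10, 20), overall = c(10, 20), text = NA,
    lang1 = "en", lang2 = "en", stringsAsFactors = FALSE))
  out <- rater_center_scores(df)
  expect_equal(out$overall, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  expect_warning(single <- rater_center_scores(mk_reviews(1)), "single")
  expect_equal(single$overall, 0)

  # opposite biases, same ranking: identical per-beer means
  two <- review_set(data.frame(
    beer_id = rep(c("b1", "b2"), 2), rater_id = rep(c("lo", "hi"), each = 2),
    appearance = 5, aroma = 5, taste = 5, palate = 5,
    overall = c(1, 2, 15, 20), text = NA, lang1 = "en", lang2 = "en",
    stringsAsFactors = FALSE))
  out2 <- suppressWarnings(rater_center_scores(two))  # constant sub-scores
  expect_equal(out2$overall, c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("text normalization collapses synonyms and protects beer terms", {
  lex <- default_lexicon()
  t1 <- normalize_text("Floral notes, flowery aroma!", lex)
  expect_equal(sum(t1 == "floral"), 2)
  t2 <- normalize_text("Lambic 75cl!!", lex)
  expect_equal(t2, "Lambic")
  expect_equal(normalize_text("", lex), character(0))
  # slang and stemming
  expect_true("great" %in% normalize_text("gr8 beer", lex))
  expect_equal(normalize_text("acidity", lex), "sour")
})

test_that("aspect classifier separates templated vocabularies", {
  train <- labeled_sentence_corpus(240, seed = 1)
  clf <- train_aspect_classifier(train$sentence, train$aspect)
  acc_train <- mean(classify_sentences(clf, train$sentence) == train$aspect)
  expect_gte(acc_train, 0.9)

  held <- labeled_sentence_corpus(120, seed = 99)
  acc_test <- mean(classify_sentences(clf, held$sentence) == held$aspect)
  expect_gte(acc_test, 0.8)

  # unseen vocabulary still yields a label
  lab <- classify_sentences(clf, "zzz qqq xyzzy")
  expect_true(lab %in% c("appearance", "aroma", "taste", "palate", "overall",
                         "irrelevant"))

  one_class <- labeled_sentence_corpus(30, seed = 2)
  one_class$aspect <- "taste"
  expect_error(train_aspect_classifier(one_class$sentence, one_class$aspect),
               "2 classes")
})

test_that("TFIDF enrichment matches the smoothed-idf hand computation", {
  classified <- data.frame(
    beer_id = c("b1", "b2"),
    sentence = c("hoppy hoppy malt", "malt"),
    aspect = "taste", stringsAsFactors = FALSE)
  m <- tfidf_enrichment(classified, default_lexicon(),
                        aspects_kept = "taste")
  # doc b1 = {hoppy, hoppy, malty}; doc b2 = {malty}; N = 2
  idf_hoppy <- log(3 / 2) + 1
  idf_malty <- log(3 / 3) + 1
  expect_equal(m["b1", "hoppy"], 2 / 3 * idf_hoppy)
  expect_equal(m["b1", "malty"], 1 / 3 * idf_malty)
  expect_equal(m["b2", "hoppy"], 0)
  expect_equal(m["b2", "malty"], 1 * idf_malty)
  # terms absent everywhere get no column
  expect_false("banana" %in% colnames(m))
  # a shared term leaves ordering to tf alone
  expect_gt(m["b2", "malty"], m["b1", "malty"])
})

test_that("TFIDF scores are non-negative and zero iff the term is absent", {
  b <- study_bundle()
  filt <- filter_reviews(b$reviews, 100)$reviews
  some <- filt[seq_len(300), ]
  class(some) <- class(filt)
  sents <- split_sentences(some)
  gold <- attr(b$reviews, "gold_sentences")
  key <- paste(gold$beer_id, gold$sentence)
  sents$aspect <- gold$aspect[match(paste(sents$beer_id, sents$sentence), key)]
  sents <- sents[!is.na(sents$aspect), ]
  m <- suppressWarnings(tfidf_enrichment(sents, default_lexicon()))
  expect_true(all(m >= 0))
  docs <- split(sents$sentence[sents$aspect %in% c("aroma", "taste")],
                sents$beer_id[sents$aspect %in% c("aroma", "taste")])
  for (beer in head(rownames(m), 10)) {
    dd <- if (is.null(docs[[beer]])) character(0) else docs[[beer]]
    toks <- unlist(lapply(dd, normalize_text))
    for (term in colnames(m)) {
      expect_equal(m[beer, term] > 0, sum(toks == term) > 0)
    }
  }
})

test_that("review-panel agreement recovers mapped attribute correlations", {
  b <- study_bundle()
  z <- suppressWarnings(taster_zscore(b$panel))
  prof <- suppressWarnings(beer_attribute_means(z))

  # profile against itself: rho exactly 1 on the diagonal pairs
  self <- as.data.frame(prof$values[, c("bitter", "sweet")])
  out_self <- review_panel_agreement(self, prof,
                                     mapping = c(bitter = "bitter",
                                                 sweet = "sweet"))
  expect_equal(out_self$rho, c(1, 1))

  filt <- filter_reviews(b$reviews, 100)$reviews
  scores <- suppressWarnings(rater_center_scores(filt))
  out <- review_panel_agreement(scores, prof,
                                mapping = c(overall = "appreciation",
                                            palate = "body",
                                            nonexistent = "bitter"))
  expect_setequal(out$review_var, c("overall", "palate"))  # unmapped dropped
  expect_gt(out$rho[out$review_var == "palate"], 0.3)
})
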