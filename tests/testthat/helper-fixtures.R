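# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the default study bundle used across modules
study_bundle <- function() cached("study_bundle", gen_bundle(seed = 42))

# a two-compound, one-style design for copula-focused tests
mini_design <- function(n_beers = 1000, rho = 0.6) {
  styles <- data.frame(style = "Blond", n_beers = n_beers, abv_lo = 6,
                       abv_hi = 7, price_shift = 0, stringsAsFactors = FALSE)
  compounds <- data.frame(
    compound = c("ethyl_acetate", "isoamyl_acetate", "ethanol"),
    origin = "yeast",
    meanlog = log(c(18, 1.8, 6)), sdlog = c(0.5, 0.6, 0.4),
    stringsAsFactors = FALSE)
  shifts <- data.frame(style = character(0), compound = character(0),
                       shift = numeric(0), stringsAsFactors = FALSE)
  structure(list(styles = styles, compounds = compounds, shifts = shifts),
            class = "flv_design")
}

mini_truth <- function(design, rho = 0.6) {
  tr <- default_ground_truth(design)
  tr$drivers <- data.frame(
    attribute = c("ester_aroma", "appreciation"),
    compound = c("ethyl_acetate", "ethyl_acetate"),
    shape = "saturating", effect_size = c(0.8, 1),
    stringsAsFactors = FALSE)
  tr$interactions <- tr$interactions[0, ]
  tr$masking <- tr$masking[0, ]
  tr$appreciation_drivers <- "ethyl_acetate"
  tr$corr$block_rho <- c(yeast = 0)
  tr$corr$overrides <- data.frame(
    comp_a = "ethyl_acetate", comp_b = "isoamyl_acetate", rho = rho,
    stringsAsFactors = FALSE)
  tr$medians <- setNames(exp(design$compounds$meanlog),
                         design$compounds$compound)
  tr$logsd <- setNames(design$compounds$sdlog, design$compounds$compound)
  tr
}

# hand-built depth-1 forest in the flat node layout of the TreeSHAP kernel:
# each element of `splits` is list(feature (1-based), threshold, left_value,
# right_value, left_cover, right_cover)
hand_forest <- function(splits) {
  feature <- integer(0); threshold <- numeric(0)
  yes <- integer(0); no <- integer(0)
  value <- numeric(0); cover <- numeric(0); roots <- integer(0)
  for (s in splits) {
    base <- length(feature)
    roots <- c(roots, base)
    feature <- c(feature, s$feature - 1L, -1L, -1L)
    threshold <- c(threshold, s$threshold, 0, 0)
    yes <- c(yes, base + 1L, -1L, -1L)
    no <- c(no, base + 2L, -1L, -1L)
    value <- c(value, 0, s$left_value, s$right_value)
    cover <- c(cover, s$left_cover + s$right_cover, s$left_cover,
               s$right_cover)
  }
  list(feature = as.integer(feature), threshold = threshold,
       yes = as.integer(yes), no = as.integer(no), value = value,
       cover = cover, roots = as.integer(roots))
}

forest_shap <- function(forest, X, base_score = 0) {
  flavorbench:::.treeshap_cpp(X, forest$feature, forest$threshold,
                              forest$yes, forest$no, forest$value,
                              forest$cover, forest$roots, base_score)
}

forest_predict <- function(forest, X, base_score = 0) {
  flavorbench:::.treepredict_cpp(X, forest$feature, forest$threshold,
                                 forest$yes, forest$no, forest$value,
                                 forest$cover, forest$roots, base_score)
}

# exhaustive Shapley values for a forest model under the empirical
# background distribution (interventional expectation over background rows)
brute_force_shap <- function(forest, x, background, base_score = 0) {
  p <- length(x)
  vfun <- function(S) {
    M <- background
    for (j in S) M[, j] <- x[j]
    mean(forest_predict(forest, M, base_score))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(mask) which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  for (j in seq_len(p)) {
    for (S in subsets) {
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (vfun(c(S, j)) - vfun(S))
    }
  }
  phi
}

# templated labeled sentences with near-disjoint aspect vocabularies,
# for classifier tests
labeled_sentence_corpus <- function(n, seed = 1) {
  set.seed(seed)
  banks <- list(
    appearance = c("Pours a deep amber colour.", "The head is thick and white.",
                   "Lovely golden appearance in the glass."),
    aroma = c("Smells hoppy and floral.", "The aroma is fruity.",
              "Strong banana aroma on the nose."),
    taste = c("Tastes bitter and malty.", "The taste is sweet with caramel.",
              "Sour taste with lemon notes."),
    palate = c("The mouthfeel is full and creamy.",
               "Thin body on the palate.", "Smooth and round mouthfeel."),
    overall = c("Overall a great beer.", "One of the best beers I have had.",
                "Overall rather disappointing."),
    irrelevant = c("Bought this bottle in Bruges.",
                   "Shared it with my brother.", "The label art is nice."))
  aspect <- sample(names(banks), n, replace = TRUE)
  sentence <- vapply(aspect, function(a) sample(banks[[a]], 1), character(1))
  data.frame(sentence = sentence, aspect = aspect, stringsAsFactors = FALSE)
}
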