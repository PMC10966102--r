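test_that("generation is byte-identical under one seed", {
  d <- mini_design(n_beers = 50)
  tr <- mini_truth(d)
  c1 <- gen_chemistry(d, tr, seed = 5)
  c2 <- gen_chemistry(d, tr, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(c1$values, gen_chemistry(d, tr, seed = 6)$values))

  b1 <- study_bundle()
  b2 <- gen_bundle(seed = b1$seed)
  expect_identical(b1$chemistry, b2$chemistry)
  expect_identical(as.data.frame(b1$panel), as.data.frame(b2$panel))
  expect_identical(as.data.frame(b1$reviews), as.data.frame(b2$reviews))
})

test_that("copula realizes target rank correlations and marginals", {
  d <- mini_design(n_beers = 1000)
  tr <- mini_truth(d, rho = 0.6)
  chem <- gen_chemistry(d, tr, seed = 11)
  emp <- cor(chem$values[, "ethyl_acetate"], chem$values[, "isoamyl_acetate"],
             method = "spearman")
  expect_lt(abs(emp - 0.6), 0.1)
  expect_true(all(chem$values >= 0))
  # zero signature shifts: log-medians sit near the marginal meanlog
  med <- apply(log(chem$values), 2, median)
  mu <- setNames(d$compounds$meanlog, d$compounds$compound)
  se <- d$compounds$sdlog * sqrt(pi / (2 * 1000))  # asymptotic median se
  expect_true(all(abs(med[names(mu)] - mu) < 4 * se))
})

test_that("non-PSD correlation blocks are rejected by name", {
  d <- mini_design(n_beers = 10)
  tr <- mini_truth(d)
  tr$corr$overrides <- data.frame(
    comp_a = c("ethyl_acetate", "ethyl_acetate", "isoamyl_acetate"),
    comp_b = c("isoamyl_acetate", "ethanol", "ethanol"),
    rho = c(0.95, 0.95, -0.9), stringsAsFactors = FALSE)
  expect_error(gen_chemistry(d, tr, seed = 1), "yeast")
})

test_that("style signature shifts move per-style medians", {
  b <- study_bundle()
  chem <- b$chemistry
  sour <- chem$beers$style %in% c("Kriek", "Lambic", "West_Flanders_ale")
  expect_gt(median(chem$values[sour, "lactic_acid"]),
            4 * median(chem$values[!sour, "lactic_acid"]))
  nonalc <- chem$beers$style == "Non_low_alcohol"
  expect_lt(max(chem$beers$abv[nonalc]), 4.2)
})

test_that("zero-noise panel scores equal the deterministic response surface", {
  d <- mini_design(n_beers = 20)
  tr <- mini_truth(d)
  chem <- gen_chemistry(d, tr, seed = 2)
  panel <- gen_panel(chem, tr, n_tasters = 1, seed = 2, n_repeat = 0,
                     noise_sd = 0, beer_noise_sd = 0, taster_scale_sd = 0,
                     taster_bias_sd = 0, score_anchor = 4, score_slope = 1)
  lat <- latent_attributes(chem, tr)
  expected <- 4 + lat[panel$beer_id, ][cbind(seq_len(nrow(panel)),
                                             match(panel$attribute,
                                                   colnames(lat)))]
  expect_equal(panel$score, pmin(7, pmax(1, expected)))
})

test_that("masking couples sweetness against bitterness", {
  b <- study_bundle()
  lat <- latent_attributes(b$chemistry, b$truth)
  expect_lt(cor(lat[, "sweet"], lat[, "bitter"], method = "spearman"), 0)
})

test_that("panel scores stay on the 7-point scale", {
  p <- study_bundle()$panel
  expect_true(all(p$score >= 1 & p$score <= 7))
})

test_that("gen_panel rejects drivers of unknown compounds", {
  d <- mini_design(n_beers = 5)
  tr <- mini_truth(d)
  tr$drivers$compound[1] <- "unobtainium"
  chem <- gen_chemistry(d, mini_truth(d), seed = 1)
  expect_error(gen_panel(chem, tr, seed = 1), "unobtainium")
})

test_that("disabled price bias removes the price-appreciation correlation", {
  design <- default_study_design()
  design$styles$price_shift <- 0
  # pin ethanol so price (a function of ABV) cannot proxy for chemistry
  design$compounds$sdlog[design$compounds$compound == "ethanol"] <- 1e-3
  truth <- default_ground_truth(design)
  cfg <- default_review_config(price_bias = 0, style_bias = c(none = 0),
                               mean_reviews = 30, nonenglish_frac = 0)
  chem <- gen_chemistry(design, truth, seed = 21)
  revs <- gen_reviews(chem, truth, cfg, seed = 21)
  mean_overall <- tapply(revs$overall, revs$beer_id, mean)
  price <- setNames(chem$beers$price_per_l, chem$beers$beer_id)
  rho <- cor(price[names(mean_overall)], mean_overall, method = "spearman")
  expect_lt(abs(rho), 0.15)

  # with the default positive bias the correlation appears
  cfg2 <- default_review_config(mean_reviews = 30, nonenglish_frac = 0,
                                style_bias = c(none = 0))
  revs2 <- gen_reviews(chem, truth, cfg2, seed = 21)
  mo2 <- tapply(revs2$overall, revs2$beer_id, mean)
  expect_gt(cor(price[names(mo2)], mo2, method = "spearman"), 0.2)
})

test_that("planted appreciation drivers leave a positive marginal trace", {
  b <- study_bundle()
  revs <- b$reviews
  mean_overall <- tapply(revs$overall, revs$beer_id, mean)
  ea <- b$chemistry$values[names(mean_overall), "ethyl_acetate"]
  expect_gt(cor(ea, mean_overall, method = "spearman"), 0.2)
})

test_that("the injected non-English fraction is removed by filtering", {
  b <- study_bundle()
  filt <- filter_reviews(b$reviews, min_reviews = 0)
  frac_removed <- filt$report$removed[1] / nrow(b$reviews)
  expect_lt(abs(frac_removed - 0.1), 0.02)
})

test_that("invalid review-count configurations error", {
  d <- mini_design(n_beers = 5)
  tr <- mini_truth(d)
  chem <- gen_chemistry(d, tr, seed = 1)
  cfg <- default_review_config(mean_reviews = -4)
  expect_error(gen_reviews(chem, default_ground_truth(), cfg, seed = 1),
               "non-negative")
})

test_that("the truth ledger lists planted drivers and survives JSON", {
  b <- study_bundle()
  ledger <- truth_ledger(b)
  expect_equal(sort(ledger$appreciation_drivers),
               sort(unique(ledger$appreciation_drivers)))
  expect_setequal(ledger$appreciation_drivers,
                  c("ethyl_acetate", "lactic_acid", "ethyl_phenyl_acetate"))
  json <- jsonlite::toJSON(ledger, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  expect_equal(back$drivers, ledger$drivers)
  expect_equal(back$noise, ledger$noise)
  expect_equal(back$correlation_overrides, ledger$correlation_overrides)
  # regenerating with the same seed gives the identical ledger
  b2 <- gen_bundle(seed = b$seed)
  expect_identical(truth_ledger(b2), ledger)
})
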