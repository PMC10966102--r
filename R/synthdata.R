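#' Default study design: styles and compound panel
#'
#' The style table mirrors the composition of the 250-beer study set
#' (22 styles; Blond 12.4%, Tripel 11.2%, Brut 2%, Faro ~1%, a dedicated
#' non/low-alcohol group) and the compound panel spans the five origin
#' classes (malt, hops, yeast, wild flora, other) with log-normal marginals
#' on realistic concentration scales. Style signature shifts plant the
#' well-known style markers: high iso-alpha acids in hoppy styles, high
#' lactic/acetic acid in sour styles, dark color in stouts, depleted esters
#' and glycerol in non/low-alcohol beers.
#'
#' @return an object of class `flv_design` with elements `styles`
#'   (style, n_beers, abv_lo, abv_hi, price_shift), `compounds`
#'   (compound, origin, meanlog, sdlog) and `shifts` (style, compound,
#'   shift in log units).
#' @export
default_study_design <- function() {
  styles <- data.frame(
    style = c("Blond", "Tripel", "Lager", "IPA", "Non_low_alcohol",
              "Strong_ale", "Dubbel", "Saison", "Wheat", "Stout", "Fruit",
              "Amber", "Christmas", "Kriek", "Pilsner", "Porter",
              "West_Flanders_ale", "Lambic", "Flanders_old_brown", "Scotch",
              "Brut", "Faro"),
    n_beers = c(31, 28, 20, 14, 14, 13, 13, 12, 12, 12, 8, 10, 8, 8, 8, 7,
                6, 6, 6, 6, 5, 3),
    abv_lo = c(6, 7.5, 4.8, 5.5, 0.1, 8, 6, 5, 4.5, 7, 3.5, 5, 8, 4, 4.8,
               5, 5, 5, 5, 7, 10.5, 4),
    abv_hi = c(7.5, 9.5, 5.4, 7, 2, 11, 7.5, 7, 5.5, 10, 6, 6.5, 10.5, 6,
               5.2, 7, 7, 6.5, 6.5, 9, 11.5, 5),
    price_shift = c(0, 0.3, -0.3, 0.1, -0.2, 0.3, 0.1, 0, -0.1, 0.1, 0.1,
                    0, 0.3, 0.25, -0.3, 0, 0.35, 0.35, 0.3, 0.2, 0.3, 0.2),
    stringsAsFactors = FALSE)
  stopifnot(sum(styles$n_beers) == 250, nrow(styles) == 22)

  cmp <- function(name, origin, med, sdlog = 0.55) {
    data.frame(compound = name, origin = origin, meanlog = log(med),
               sdlog = sdlog, stringsAsFactors = FALSE)
  }
  compounds <- rbind(
    cmp("ethanol", "yeast", 6, 0.5),
    cmp("glycerol", "yeast", 1800, 0.5),
    cmp("ethyl_acetate", "yeast", 18, 0.55),
    cmp("ethyl_hexanoate", "yeast", 0.2, 0.6),
    cmp("ethyl_octanoate", "yeast", 0.35, 0.6),
    cmp("ethyl_decanoate", "yeast", 0.08, 0.7),
    cmp("isoamyl_acetate", "yeast", 1.8, 0.6),
    cmp("phenethyl_acetate", "yeast", 0.4, 0.6),
    cmp("ethyl_phenyl_acetate", "yeast", 0.12, 0.6),
    cmp("ethyl_butyrate", "yeast", 0.08, 0.6),
    cmp("isoamyl_alcohol", "yeast", 60, 0.45),
    cmp("isobutanol", "yeast", 14, 0.5),
    cmp("propanol", "yeast", 18, 0.5),
    cmp("phenethyl_alcohol", "yeast", 25, 0.5),
    cmp("acetaldehyde", "yeast", 4, 0.6),
    cmp("diacetyl", "yeast", 0.03, 0.7),
    do.call(rbind, lapply(1:9, function(i)
      cmp(sprintf("yeast_metab_%02d", i), "yeast", 0.5 * i, 0.6))),
    cmp("iso_alpha_acids", "hops", 20, 0.7),
    cmp("linalool", "hops", 0.02, 0.7),
    cmp("citronellol", "hops", 0.008, 0.7),
    cmp("geraniol", "hops", 0.006, 0.7),
    cmp("alpha_terpineol", "hops", 0.004, 0.7),
    cmp("myrcene", "hops", 0.012, 0.75),
    cmp("humulene", "hops", 0.01, 0.75),
    cmp("limonene", "hops", 0.005, 0.7),
    cmp("beta_pinene", "hops", 0.003, 0.7),
    cmp("caryophyllene", "hops", 0.004, 0.7),
    do.call(rbind, lapply(1:15, function(i)
      cmp(sprintf("hop_terpenoid_%02d", i), "hops", 0.002 + 0.003 * i, 0.7))),
    cmp("maltose", "malt", 9000, 0.6),
    cmp("glucose", "malt", 1200, 0.6),
    cmp("fructose", "malt", 800, 0.6),
    cmp("sucrose", "malt", 300, 0.7),
    cmp("protein", "malt", 4500, 0.35),
    cmp("beta_glucan", "malt", 180, 0.5),
    cmp("color", "malt", 14, 0.7),
    cmp("polyphenols", "malt", 150, 0.4),
    do.call(rbind, lapply(1:12, function(i)
      cmp(sprintf("malt_comp_%02d", i), "malt", 5 * i, 0.5))),
    cmp("lactic_acid", "wild", 180, 1.0),
    cmp("acetic_acid", "wild", 90, 0.9),
    cmp("ethyl_phenol_4", "wild", 0.05, 0.9),
    cmp("ethyl_guaiacol_4", "wild", 0.02, 0.9),
    cmp("gluconic_acid", "wild", 50, 0.9),
    do.call(rbind, lapply(1:5, function(i)
      cmp(sprintf("wild_comp_%02d", i), "wild", 0.1 * i, 0.8))),
    cmp("vinyl_guaiacol_4", "other", 0.15, 0.7),
    cmp("methanethiol", "other", 0.0015, 0.7),
    cmp("dms", "other", 0.02, 0.6),
    cmp("sulfite", "other", 8, 0.6),
    cmp("iron", "other", 0.08, 0.5),
    cmp("ammonia", "other", 6, 0.5),
    cmp("ph", "other", 4.3, 0.05),
    cmp("co2", "other", 5.2, 0.12),
    do.call(rbind, lapply(1:12, function(i)
      cmp(sprintf("other_comp_%02d", i), "other", 0.2 * i, 0.6)))
  )
  rownames(compounds) <- NULL
  stopifnot(nrow(compounds) == 100)

  shift <- function(style, compound, s)
    data.frame(style = style, compound = compound, shift = s,
               stringsAsFactors = FALSE)
  sour <- c("Kriek", "Lambic", "Faro", "West_Flanders_ale",
            "Flanders_old_brown", "Fruit")
  dark <- c("Stout", "Porter", "Scotch")
  strong <- c("Tripel", "Strong_ale", "Christmas", "Brut")
  shifts <- rbind(
    shift("IPA", "iso_alpha_acids", 0.9),
    do.call(rbind, lapply(c("linalool", "citronellol", "geraniol", "myrcene",
                            "humulene", "alpha_terpineol"), function(cc)
      shift("IPA", cc, 0.8))),
    shift("Pilsner", "iso_alpha_acids", 0.4),
    do.call(rbind, lapply(sour, function(s) rbind(
      shift(s, "lactic_acid", 2.2), shift(s, "acetic_acid", 1.5),
      shift(s, "iso_alpha_acids", -0.9),
      shift(s, "ethyl_phenol_4", 1.2), shift(s, "gluconic_acid", 1.0)))),
    do.call(rbind, lapply(dark, function(s) rbind(
      shift(s, "color", 1.2), shift(s, "maltose", 0.4),
      shift(s, "protein", 0.3)))),
    do.call(rbind, lapply(strong, function(s) rbind(
      shift(s, "ethyl_acetate", 0.5), shift(s, "isoamyl_acetate", 0.5),
      shift(s, "glycerol", 0.3)))),
    shift("Non_low_alcohol", "ethyl_acetate", -1.2),
    shift("Non_low_alcohol", "isoamyl_acetate", -1.2),
    shift("Non_low_alcohol", "ethyl_hexanoate", -1.2),
    shift("Non_low_alcohol", "glycerol", -0.8),
    shift("Non_low_alcohol", "maltose", 0.5),
    shift("Wheat", "vinyl_guaiacol_4", 0.8),
    do.call(rbind, lapply(c("Christmas", "Saison"), function(s) rbind(
      shift(s, "geraniol", 0.8), shift(s, "citronellol", 0.6))))
  )
  # ethanol marginal follows each style's ABV window
  mu_eth <- compounds$meanlog[compounds$compound == "ethanol"]
  eth <- data.frame(style = styles$style, compound = "ethanol",
                    shift = log((styles$abv_lo + styles$abv_hi) / 2) - mu_eth,
                    stringsAsFactors = FALSE)
  shifts <- rbind(shifts, eth)
  rownames(shifts) <- NULL
  structure(list(styles = styles, compounds = compounds, shifts = shifts),
            class = "flv_design")
}

#' @export
print.flv_design <- function(x, ...) {
  cat(sprintf("<flv_design> %d styles, %d beers, %d compounds\n",
              nrow(x$styles), sum(x$styles$n_beers), nrow(x$compounds)))
  invisible(x)
}

#' Planted ground truth for synthetic studies
#'
#' Defines the sensory response surfaces (Hill-type saturating terms,
#' linear terms and pairwise interactions per attribute), the antagonistic
#' masking couplings (sweetness suppressed by bitterness), the compound
#' rank-correlation structure (within-origin base correlations plus pair
#' overrides, e.g. ethanol-ethyl acetate 0.72, iso-alpha acids
#' anti-correlated with lactic and acetic acid), the planted appreciation
#' drivers, and the noise scales.
#'
#' @param design an `flv_design` (used to pin Hill half-saturation
#'   constants at the global compound medians).
#' @return an object of class `flv_truth`.
#' @export
default_ground_truth <- function(design = default_study_design()) {
  drv <- function(attribute, compound, shape, es)
    data.frame(attribute = attribute, compound = compound, shape = shape,
               effect_size = es, stringsAsFactors = FALSE)
  drivers <- rbind(
    drv("hop_aroma", "linalool", "saturating", 0.9),
    drv("hop_aroma", "citronellol", "saturating", 0.5),
    drv("hop_aroma", "geraniol", "saturating", 0.4),
    drv("hop_aroma", "myrcene", "saturating", 0.3),
    drv("hop_taste", "linalool", "saturating", 0.85),
    drv("hop_taste", "citronellol", "saturating", 0.5),
    drv("hop_taste", "myrcene", "saturating", 0.25),
    drv("hop_taste", "iso_alpha_acids", "saturating", 0.35),
    drv("bitter", "iso_alpha_acids", "saturating", 1.1),
    drv("sweet", "maltose", "saturating", 0.8),
    drv("sweet", "glucose", "saturating", 0.4),
    drv("sour", "lactic_acid", "saturating", 0.9),
    drv("sour", "acetic_acid", "saturating", 0.5),
    drv("malt_taste", "color", "saturating", 0.6),
    drv("malt_taste", "maltose", "saturating", 0.5),
    drv("ester_aroma", "ethyl_acetate", "saturating", 0.7),
    drv("ester_aroma", "isoamyl_acetate", "saturating", 0.6),
    drv("ester_aroma", "ethyl_hexanoate", "saturating", 0.4),
    drv("banana_ester", "isoamyl_acetate", "saturating", 0.9),
    drv("floral_aroma", "geraniol", "saturating", 0.6),
    drv("floral_aroma", "citronellol", "saturating", 0.4),
    drv("floral_aroma", "phenethyl_acetate", "saturating", 0.4),
    drv("alcohol", "ethanol", "linear", 1.0),
    drv("body", "glycerol", "saturating", 0.6),
    drv("body", "protein", "saturating", 0.5),
    drv("body", "ethanol", "linear", 0.4),
    drv("appearance", "color", "saturating", 0.8),
    drv("appreciation", "ethyl_acetate", "saturating", 1.0),
    drv("appreciation", "lactic_acid", "saturating", 0.7),
    drv("appreciation", "ethyl_phenyl_acetate", "linear", 0.6)
  )
  interactions <- data.frame(
    attribute = "ester_aroma", compound_a = "ethyl_acetate",
    compound_b = "isoamyl_acetate", effect_size = 0.3,
    stringsAsFactors = FALSE)
  masking <- data.frame(attribute = "sweet", other = "bitter",
                        coupling = -0.45, stringsAsFactors = FALSE)
  ov <- function(a, b, rho)
    data.frame(comp_a = a, comp_b = b, rho = rho, stringsAsFactors = FALSE)
  overrides <- rbind(
    ov("ethanol", "ethyl_acetate", 0.72),
    ov("ethanol", "glycerol", 0.70),
    ov("ethyl_acetate", "ethyl_hexanoate", 0.68),
    ov("citronellol", "alpha_terpineol", 0.57),
    ov("citronellol", "linalool", 0.39),
    ov("iso_alpha_acids", "linalool", 0.16),
    ov("iso_alpha_acids", "citronellol", 0.16),
    ov("iso_alpha_acids", "alpha_terpineol", -0.07),
    # bittering acids vary near-independently of the aroma terpenoids
    # (early vs late hop additions), unlike the rest of the hops block
    do.call(rbind, lapply(
      c("myrcene", "humulene", "limonene", "beta_pinene", "caryophyllene",
        sprintf("hop_terpenoid_%02d", 1:15)),
      function(cc) ov("iso_alpha_acids", cc, 0.15))),
    ov("iso_alpha_acids", "lactic_acid", -0.45),
    ov("iso_alpha_acids", "acetic_acid", -0.40),
    ov("lactic_acid", "acetic_acid", 0.66),
    ov("ethyl_phenyl_acetate", "phenethyl_acetate", 0.55)
  )
  structure(list(
    drivers = drivers,
    interactions = interactions,
    masking = masking,
    appreciation_drivers =
      drivers$compound[drivers$attribute == "appreciation"],
    corr = list(block_rho = c(malt = 0.30, hops = 0.35, yeast = 0.50,
                              wild = 0.50, other = 0.05),
                overrides = overrides),
    hill = list(h = 2),
    noise = list(taster_sd = 0.5, beer_sd = 0.3, review_sd = 1.2),
    medians = setNames(exp(design$compounds$meanlog), design$compounds$compound),
    logsd = setNames(design$compounds$sdlog, design$compounds$compound)
  ), class = "flv_truth")
}

# target Spearman matrix implied by a truth object, for a compound set
.target_spearman <- function(truth, compounds_df) {
  p <- nrow(compounds_df)
  S <- diag(p)
  rownames(S) <- colnames(S) <- compounds_df$compound
  for (blk in unique(compounds_df$origin)) {
    idx <- which(compounds_df$origin == blk)
    base <- truth$corr$block_rho[[blk]] %||% 0
    S[idx, idx] <- base
    diag(S)[idx] <- 1
  }
  ovr <- truth$corr$overrides
  for (i in seq_len(nrow(ovr))) {
    a <- ovr$comp_a[i]; b <- ovr$comp_b[i]
    if (a %in% rownames(S) && b %in% rownames(S)) {
      S[a, b] <- S[b, a] <- ovr$rho[i]
    }
  }
  S
}

.check_psd <- function(M, what) {
  ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  stop_if(ev < -1e-8, sprintf(
    "correlation block '%s' is not positive semi-definite (min eigenvalue %.3g)",
    what, ev))
}

#' Generate a synthetic compound matrix
#'
#' Concentrations follow a Gaussian copula with log-normal marginals: a
#' latent multivariate normal realizes the target Spearman rank
#' correlations (latent Pearson r equal to `2 * sin(pi * rho / 6)`), and
#' per-style additive log-shifts move compound medians to plant style
#' signatures. ABV is the generated ethanol value; a price per liter
#' correlated with style and strength is attached.
#'
#' @param design an `flv_design` (styles x compounds x shifts).
#' @param truth an `flv_truth` carrying the correlation structure.
#' @param seed integer seed; identical inputs and seed give a
#'   byte-identical matrix.
#' @return a [compound_matrix()].
#' @export
gen_chemistry <- function(design = default_study_design(),
                          truth = default_ground_truth(design), seed = 1) {
  stopifnot(inherits(design, "flv_design"), inherits(truth, "flv_truth"))
  stop_if(any(design$styles$n_beers < 1), "every style needs n_beers >= 1")
  stop_if(any(design$compounds$sdlog <= 0), "compound log-sd must be > 0")
  set.seed(stage_seed(seed, "chemistry"))
  cdf <- design$compounds
  S <- .target_spearman(truth, cdf)
  R <- 2 * sin(pi * S / 6)
  diag(R) <- 1
  for (blk in unique(cdf$origin)) {
    idx <- which(cdf$origin == blk)
    .check_psd(R[idx, idx], blk)
  }
  .check_psd(R, "assembled")
  L <- chol(R + diag(1e-10, nrow(R)))
  n <- sum(design$styles$n_beers)
  p <- nrow(cdf)
  Z <- matrix(rnorm(n * p), n, p) %*% L
  U <- pnorm(Z)
  style <- rep(design$styles$style, design$styles$n_beers)
  shift_m <- matrix(0, n, p, dimnames = list(NULL, cdf$compound))
  for (i in seq_len(nrow(design$shifts))) {
    sh <- design$shifts[i, ]
    shift_m[style == sh$style, sh$compound] <-
      shift_m[style == sh$style, sh$compound] + sh$shift
  }
  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, cdf$compound))
  for (j in seq_len(p)) {
    vals[, j] <- qlnorm(U[, j], meanlog = cdf$meanlog[j] + shift_m[, j],
                        sdlog = cdf$sdlog[j])
  }
  abv <- pmax(vals[, "ethanol"], 0.03)
  price <- round(exp(0.6 + 0.35 * log(abv + 0.5) +
                       rep(design$styles$price_shift, design$styles$n_beers) +
                       rnorm(n, 0, 0.25)), 2)
  beers <- data.frame(
    beer_id = sprintf("beer_%03d", seq_len(n)),
    style = style, abv = abv, price_per_l = price,
    stringsAsFactors = FALSE)
  pm <- data.frame(property = cdf$compound, origin = cdf$origin,
                   aggregate = FALSE, stringsAsFactors = FALSE)
  compound_matrix(beers, vals, pm)
}

# saturating response centered at the half-saturation point, range (-1, 1)
.hill <- function(x, K, h) 2 * (x^h / (K^h + x^h) - 0.5)

#' Latent sensory attribute surface
#'
#' The deterministic part of every synthetic sensory response: a sum of
#' Hill-type saturating terms and standardized-log linear terms over the
#' driver compounds, plus planted pairwise interactions, with antagonistic
#' masking couplings applied last.
#'
#' @param chem a [compound_matrix()].
#' @param truth an `flv_truth`.
#' @return matrix beers x attributes of latent intensities.
#' @export
latent_attributes <- function(chem, truth) {
  vals <- chem$values
  g <- function(compound, shape) {
    stop_if(!compound %in% colnames(vals),
            "driver references unknown compound: ", compound)
    x <- vals[, compound]
    if (shape == "saturating") {
      .hill(x, truth$medians[[compound]], truth$hill$h)
    } else {
      (log(pmax(x, 1e-12)) - log(truth$medians[[compound]])) /
        truth$logsd[[compound]]
    }
  }
  attrs <- unique(truth$drivers$attribute)
  lat <- matrix(0, nrow(vals), length(attrs),
                dimnames = list(rownames(vals), attrs))
  for (i in seq_len(nrow(truth$drivers))) {
    d <- truth$drivers[i, ]
    lat[, d$attribute] <- lat[, d$attribute] +
      d$effect_size * g(d$compound, d$shape)
  }
  for (i in seq_len(nrow(truth$interactions))) {
    ix <- truth$interactions[i, ]
    lat[, ix$attribute] <- lat[, ix$attribute] +
      ix$effect_size * g(ix$compound_a, "saturating") *
        g(ix$compound_b, "saturating")
  }
  for (i in seq_len(nrow(truth$masking))) {
    m <- truth$masking[i, ]
    lat[, m$attribute] <- lat[, m$attribute] + m$coupling * lat[, m$other]
  }
  lat
}

#' Generate trained-panel scores for a synthetic chemistry
#'
#' Beers are tasted in style-grouped sessions by a panel of `n_tasters`;
#' not every taster attends every session. The observed score is the
#' latent response surface mapped onto the 7-point scale through each
#' taster's personal scale and bias, plus noise, clipped to 1..7. A
#' subset of beers is repeated in a second session for consistency
#' analysis.
#'
#' @param chem a [compound_matrix()].
#' @param truth an `flv_truth`.
#' @param n_tasters panel size (the study panel had 16).
#' @param seed integer seed.
#' @param n_repeat number of beers served twice (the study repeated 12).
#' @param noise_sd taster noise; defaults to the truth's `taster_sd`.
#' @param beer_noise_sd beer-level perceptual noise shared by all tasters
#'   and sessions (unmodeled matrix effects); defaults to the truth's
#'   `beer_sd`. Constant per beer, so it does not degrade panel
#'   consistency across sessions.
#' @param taster_scale_sd,taster_bias_sd spread of per-taster scale and
#'   bias; set to 0 for identical tasters.
#' @param score_anchor,score_slope affine map from latent units to the
#'   7-point scale.
#' @return an [panel_scores()] object with attribute `repeated_ids`.
#' @export
gen_panel <- function(chem, truth, n_tasters = 16, seed = 1, n_repeat = 12,
                      noise_sd = truth$noise$taster_sd,
                      beer_noise_sd = truth$noise$beer_sd %||% 0,
                      taster_scale_sd = 0.15, taster_bias_sd = 0.4,
                      score_anchor = 4, score_slope = 1.3) {
  stopifnot(inherits(chem, "flv_chem"), n_tasters >= 1)
  stop_if(nrow(chem$values) == 0, "chemistry is empty")
  set.seed(stage_seed(seed, "panel"))
  lat <- latent_attributes(chem, truth)
  lat <- lat + matrix(rnorm(length(lat), 0, beer_noise_sd), nrow(lat))
  beers <- chem$beers$beer_id
  n <- length(beers)
  ord <- order(chem$beers$style, beers)
  session_of <- integer(n)
  session_of[ord] <- (seq_len(n) - 1) %/% 10 + 1
  n_repeat <- min(n_repeat, n)
  repeated <- sort(sample(beers, n_repeat))
  extra_session <- max(session_of) + ((seq_len(n_repeat) - 1) %/% 6 + 1)
  tasters <- sprintf("taster_%02d", seq_len(n_tasters))
  t_scale <- exp(rnorm(n_tasters, 0, taster_scale_sd))
  t_bias <- rnorm(n_tasters, 0, taster_bias_sd)
  attrs <- colnames(lat)
  serving <- data.frame(beer = c(beers, repeated),
                        session = c(session_of, extra_session),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(serving))
  for (k in seq_len(nrow(serving))) {
    b <- serving$beer[k]
    present <- sort(sample(seq_len(n_tasters),
                           max(1, round(n_tasters * runif(1, 0.7, 1)))))
    li <- lat[b, ]
    block <- expand.grid(taster = present, attribute = attrs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    raw <- score_anchor + score_slope * li[block$attribute] *
      t_scale[block$taster] + t_bias[block$taster] +
      rnorm(nrow(block), 0, noise_sd)
    rows[[k]] <- data.frame(
      beer_id = b, taster_id = tasters[block$taster],
      session_id = sprintf("session_%02d", serving$session[k]),
      attribute = block$attribute,
      score = pmin(7, pmax(1, raw)), stringsAsFactors = FALSE)
  }
  out <- panel_scores(do.call(rbind, rows))
  attr(out, "repeated_ids") <- repeated
  out
}

#' Default configuration for the synthetic review corpus
#'
#' Scales the public-review corpus down to a testable size (about 40
#' reviews per beer instead of the platform's ~900) while keeping its
#' structure: a heavy-tailed rater activity distribution (a small core of
#' prolific raters above the activity filter, a long tail below it),
#' per-rater bias and scale, style appreciation biases (lagers and
#' non/low-alcohol beers rated harshly, strong ales favourably), a price
#' bias, and a fraction of non-English reviews for filter testing.
#'
#' @param mean_reviews negative-binomial mean of per-beer review counts.
#' @param size negative-binomial size (dispersion) parameter.
#' @param min_count guaranteed minimum reviews per beer (must be >= 0).
#' @param n_heavy,n_light sizes of the prolific and occasional rater pools.
#' @param p_heavy probability a review comes from the prolific pool.
#' @param rater_bias_sd,rater_scale_sd spread of rater effects.
#' @param price_bias coefficient of standardized log price on the overall
#'   score.
#' @param style_bias named numeric vector of per-style appreciation
#'   offsets.
#' @param noise_sd review-level noise.
#' @param nonenglish_frac fraction of reviews written in another language.
#' @return a list, validated by [gen_reviews()].
#' @export
default_review_config <- function(mean_reviews = 40, size = 3, min_count = 5,
                                  n_heavy = 55, n_light = 300, p_heavy = 0.82,
                                  rater_bias_sd = 0.6, rater_scale_sd = 0.2,
                                  price_bias = 0.35,
                                  style_bias = c(Lager = -0.5, Pilsner = -0.4,
                                                 Non_low_alcohol = -0.9,
                                                 Strong_ale = 0.3),
                                  noise_sd = 1.2, nonenglish_frac = 0.1) {
  list(mean_reviews = mean_reviews, size = size, min_count = min_count,
       n_heavy = n_heavy, n_light = n_light, p_heavy = p_heavy,
       rater_bias_sd = rater_bias_sd, rater_scale_sd = rater_scale_sd,
       price_bias = price_bias, style_bias = style_bias, noise_sd = noise_sd,
       nonenglish_frac = nonenglish_frac)
}

# sentence templates; {T} slots are filled with sensory terms whose usage
# probability tracks the matching latent attribute
.aspect_terms <- list(
  aroma = c(hoppy = "hop_aroma", fruity = "ester_aroma",
            banana = "banana_ester", floral = "floral_aroma"),
  taste = c(bitter = "bitter", sweet = "sweet", sour = "sour",
            malty = "malt_taste"),
  palate = c(full = "body", alcoholic = "alcohol")
)

.term_variants <- list(
  hoppy = c("hoppy", "hops", "hoppiness"), fruity = c("fruity", "fruit"),
  banana = c("banana", "bananas"), floral = c("floral", "flowery", "flower"),
  bitter = c("bitter", "bitterness"), sweet = c("sweet", "sweetness"),
  sour = c("sour", "tart", "acidity"), malty = c("malty", "malt"),
  full = c("full", "thick"), alcoholic = c("alcoholic", "boozy")
)

.gen_sentence <- function(aspect, z) {
  pick_term <- function(pool) {
    zs <- z[unname(pool)]
    w <- plogis(1.6 * zs)
    key <- names(pool)[sample.int(length(pool), 1, prob = w / sum(w))]
    variants <- .term_variants[[key]]
    variants[sample.int(length(variants), 1)]
  }
  txt <- switch(aspect,
    aroma = {
      t1 <- pick_term(.aspect_terms$aroma)
      if (runif(1) < 0.4) sprintf("The aroma is clearly %s.", t1)
      else sprintf("Smells %s with a hint of %s.", t1,
                   pick_term(.aspect_terms$aroma))
    },
    taste = {
      t1 <- pick_term(.aspect_terms$taste)
      if (runif(1) < 0.5) sprintf("Tastes quite %s.", t1)
      else sprintf("The taste is %s with a %s finish.", t1,
                   pick_term(.aspect_terms$taste))
    },
    palate = sprintf("The mouthfeel is %s on the palate.",
                     pick_term(.aspect_terms$palate)),
    appearance = sprintf("Pours a %s colour with a nice head.",
                         if (z["appearance"] > 0) "deep dark" else "pale golden"),
    overall = sprintf("Overall a %s beer.",
                      if (z["appreciation"] > 0.3) "great"
                      else if (z["appreciation"] < -0.3) "poor" else "decent"),
    irrelevant = sample(c("Drank this at the pub with friends.",
                          "Bought a bottle from the local shop yesterday.",
                          "Bottle number 375 in my collection.",
                          "Reminds me of my trip to Brussels."), 1)
  )
  if (runif(1) < 0.04) txt <- paste(txt, "Reminds me of Chimay.")
  if (runif(1) < 0.05) txt <- sub("great", "gr8", sub("sweet", "sweeet", txt))
  txt
}

.foreign_texts <- c("Une biere tres agreable et equilibree.",
                    "Ein wirklich gutes Bier mit viel Aroma.",
                    "Heerlijk bier met een mooie afdronk.",
                    "Una cerveza excelente y compleja.")

#' Generate a synthetic consumer-review corpus
#'
#' The overall score is a planted appreciation function of chemistry plus
#' style bias, price bias, rater bias/scale and noise; the four remaining
#' sub-scores track the matching latent attributes. Review texts are
#' template sentences whose sensory-term usage rates increase with the
#' corresponding latent attribute; the generator keeps the gold aspect
#' label of every sentence (attribute `gold_sentences`) so classifier
#' tests need no manual annotation. A configurable fraction of non-English
#' reviews and a long tail of low-activity raters are injected for filter
#' testing.
#'
#' @param chem a [compound_matrix()].
#' @param truth an `flv_truth`.
#' @param cfg a [default_review_config()] list.
#' @param seed integer seed.
#' @return an [review_set()] with attributes `gold_sentences` and
#'   `rater_pool`.
#' @export
gen_reviews <- function(chem, truth, cfg = default_review_config(), seed = 1) {
  stopifnot(inherits(chem, "flv_chem"))
  stop_if(cfg$mean_reviews <= 0 || cfg$min_count < 0,
          "review-count distribution must have non-negative support")
  set.seed(stage_seed(seed, "reviews"))
  lat <- latent_attributes(chem, truth)
  # z-scale latents so biases and noise are in comparable units
  zlat <- scale(lat)
  zlat[is.nan(zlat)] <- 0
  beers <- chem$beers
  n <- nrow(beers)
  sb <- setNames(rep(0, n), beers$beer_id)
  hit <- beers$style %in% names(cfg$style_bias)
  sb[hit] <- cfg$style_bias[beers$style[hit]]
  zprice <- as.numeric(scale(log(beers$price_per_l)))
  overall_lat <- zlat[, "appreciation"] + sb + cfg$price_bias * zprice
  sub_lat <- cbind(
    appearance = zlat[, "appearance"],
    aroma = 0.6 * zlat[, "ester_aroma"] + 0.5 * zlat[, "hop_aroma"] +
      0.2 * zlat[, "floral_aroma"],
    taste = 0.4 * zlat[, "bitter"] + 0.35 * zlat[, "sweet"] +
      0.35 * zlat[, "sour"] + 0.3 * zlat[, "malt_taste"],
    palate = zlat[, "body"])
  raters <- c(sprintf("heavy_%03d", seq_len(cfg$n_heavy)),
              sprintf("light_%03d", seq_len(cfg$n_light)))
  r_bias <- setNames(rnorm(length(raters), 0, cfg$rater_bias_sd), raters)
  r_scale <- setNames(exp(rnorm(length(raters), 0, cfg$rater_scale_sd)), raters)
  counts <- cfg$min_count + rnbinom(n, mu = cfg$mean_reviews, size = cfg$size)
  total <- sum(counts)
  beer_idx <- rep(seq_len(n), counts)
  heavy <- runif(total) < cfg$p_heavy
  rater <- ifelse(heavy,
                  sprintf("heavy_%03d", sample.int(cfg$n_heavy, total, TRUE)),
                  sprintf("light_%03d", sample.int(cfg$n_light, total, TRUE)))
  score_of <- function(latv, idx) {
    raw <- 6 + 1.2 * latv[idx] * r_scale[rater] + r_bias[rater] +
      rnorm(total, 0, cfg$noise_sd)
    pmin(10, pmax(1, raw))
  }
  rec <- data.frame(
    beer_id = beers$beer_id[beer_idx], rater_id = rater,
    appearance = score_of(sub_lat[, "appearance"], beer_idx),
    aroma = score_of(sub_lat[, "aroma"], beer_idx),
    taste = score_of(sub_lat[, "taste"], beer_idx),
    palate = score_of(sub_lat[, "palate"], beer_idx),
    overall = score_of(overall_lat, beer_idx),
    text = NA_character_, lang1 = "en", lang2 = "en",
    stringsAsFactors = FALSE)
  aspects <- c("aroma", "taste", "palate", "appearance", "overall",
               "irrelevant")
  aspect_p <- c(0.28, 0.28, 0.1, 0.12, 0.12, 0.1)
  gold <- vector("list", total)
  foreign <- runif(total) < cfg$nonenglish_frac
  for (i in seq_len(total)) {
    if (foreign[i]) {
      rec$text[i] <- sample(.foreign_texts, 1)
      if (runif(1) < 0.6) {
        rec$lang1[i] <- rec$lang2[i] <- sample(c("fr", "de", "nl", "es"), 1)
      } else {
        rec$lang2[i] <- sample(c("fr", "de", "nl"), 1)  # detector disagreement
      }
      next
    }
    z <- zlat[beer_idx[i], ]
    z["appreciation"] <- overall_lat[beer_idx[i]]
    ns <- sample(1:4, 1)
    asp <- sample(aspects, ns, replace = TRUE, prob = aspect_p)
    sent <- vapply(asp, .gen_sentence, character(1), z = z)
    rec$text[i] <- paste(sent, collapse = " ")
    gold[[i]] <- data.frame(review = i, beer_id = rec$beer_id[i],
                            sentence = sent, aspect = asp,
                            stringsAsFactors = FALSE)
  }
  out <- review_set(rec)
  attr(out, "gold_sentences") <- do.call(rbind, gold)
  attr(out, "rater_pool") <- raters
  out
}

#' Generate a complete synthetic study bundle
#'
#' Chemistry, trained-panel scores and consumer reviews over a shared beer
#' set, together with the planted ground truth. One seed fans out
#' deterministically to the three generators; the same seed regenerates a
#' byte-identical bundle.
#'
#' @param seed integer seed.
#' @param design an `flv_design`.
#' @param truth an `flv_truth`.
#' @param n_tasters panel size.
#' @param review_cfg a [default_review_config()] list.
#' @param ... further arguments passed to [gen_panel()].
#' @return an object of class `flv_bundle`.
#' @export
gen_bundle <- function(seed = 1, design = default_study_design(),
                       truth = default_ground_truth(design), n_tasters = 16,
                       review_cfg = default_review_config(), ...) {
  chem <- gen_chemistry(design, truth, seed)
  panel <- gen_panel(chem, truth, n_tasters = n_tasters, seed = seed, ...)
  reviews <- gen_reviews(chem, truth, cfg = review_cfg, seed = seed)
  structure(list(chemistry = chem, panel = panel, reviews = reviews,
                 truth = truth, design = design, seed = seed),
            class = "flv_bundle")
}

#' @export
print.flv_bundle <- function(x, ...) {
  cat(sprintf("<flv_bundle> seed %d\n", x$seed))
  print(x$chemistry)
  cat(sprintf("  panel: %d records | reviews: %d records\n",
              nrow(x$panel), nrow(x$reviews)))
  invisible(x)
}

#' Ledger of the planted ground truth
#'
#' Returns the exact drivers, effect shapes, couplings and noise scales
#' used to generate a bundle, as a plain JSON-serializable list, so
#' recovery tests can compare model dissection output against what was
#' planted.
#'
#' @param bundle an `flv_bundle`.
#' @return a named list that round-trips through JSON unchanged.
#' @export
truth_ledger <- function(bundle) {
  stopifnot(inherits(bundle, "flv_bundle"))
  tr <- bundle$truth
  list(seed = bundle$seed,
       drivers = tr$drivers,
       interactions = tr$interactions,
       masking = tr$masking,
       appreciation_drivers = tr$appreciation_drivers,
       correlation_overrides = tr$corr$overrides,
       block_rho = as.list(tr$corr$block_rho),
       noise = tr$noise)
}
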