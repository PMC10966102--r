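#' Default pipeline configuration
#'
#' A run either generates a synthetic study (`synth` block) or loads real
#' tables (`input` block with `chemistry`, `panel`, `reviews` paths) --
#' exactly one of the two. The remaining fields control the split, the
#' benchmarked families, dissection and spiking.
#'
#' @param seed mandatory integer seed for the whole run.
#' @param out_dir output directory for artifacts.
#' @param families model families to benchmark.
#' @param grids optional named list (family -> hyperparameter grid)
#'   overriding the default grids, e.g. to pin single configurations.
#' @param train_frac split fraction.
#' @param synth synthetic-generation block (or `NULL` when loading data).
#' @param input named list of file paths (or `NULL` when synthesizing).
#' @param spike_style,spike_statistic,spike_exclude spiking options.
#' @param target which appreciation target drives dissection and spiking:
#'   "reviews" (consumer overall) or "panel".
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(seed, out_dir = tempfile("flavorbench_run_"),
                            families = c("Lasso", "GBR", "RF"),
                            grids = NULL,
                            train_frac = 0.7,
                            synth = list(), input = NULL,
                            spike_style = "Blond",
                            spike_statistic = "p95",
                            spike_exclude = character(0),
                            target = c("reviews", "panel")) {
  list(seed = seed, out_dir = out_dir, families = families, grids = grids,
       train_frac = train_frac, synth = synth, input = input,
       spike_style = spike_style, spike_statistic = spike_statistic,
       spike_exclude = spike_exclude, target = match.arg(target))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  schema <- lapply(df, function(col) class(col)[1])
  jsonlite::write_json(list(columns = schema, rows = nrow(df)),
                       paste0(path, ".schema.json"), auto_unbox = TRUE)
  c(path, paste0(path, ".schema.json"))
}

#' Run the full chemistry-to-flavor pipeline
#'
#' Sequences the whole study on one seed: data (synthetic or loaded),
#' preprocessing, compound and sensory correlation matrices, panel
#' normalization and consistency, review filtering/centering/text mining
#' and review-panel agreement, the model benchmark, dissection of the
#' best tree model (MDI, TreeSHAP, PDP, importance-vs-correlation), a
#' spiking plan with predicted uplift, and a machine-readable manifest.
#' Identical config + seed reproduce identical artifacts.
#'
#' @param cfg a [pipeline_config()] list, or the path of a YAML file with
#'   the same fields.
#' @return list of in-memory results (invisibly written to
#'   `cfg$out_dir`): see the manifest for the artifact listing.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stop_if(is.null(cfg$seed), "config must carry a seed")
  has_synth <- !is.null(cfg$synth)
  has_input <- !is.null(cfg$input)
  stop_if(has_synth == has_input,
          "config must contain exactly one of 'synth' and 'input'")
  out_dir <- cfg$out_dir %||% tempfile("flavorbench_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  seed <- cfg$seed

  data <- .stage("data", {
    if (has_synth) {
      bundle <- gen_bundle(seed = seed)
      list(chem = bundle$chemistry, panel = bundle$panel,
           reviews = bundle$reviews, truth = bundle$truth)
    } else {
      list(chem = load_chemistry(cfg$input$chemistry),
           panel = panel_scores(read.csv(cfg$input$panel,
                                         stringsAsFactors = FALSE)),
           reviews = read_reviews_jsonl(cfg$input$reviews),
           truth = NULL)
    }
  })

  panel_out <- .stage("panel", {
    z <- taster_zscore(data$panel)
    profile <- suppressWarnings(beer_attribute_means(z))
    rep_ids <- attr(data$panel, "repeated_ids")
    consistency <- if (!is.null(rep_ids))
      panel_consistency(z, rep_ids) else NULL
    list(profile = profile, consistency = consistency)
  })

  reviews_out <- .stage("reviews", {
    filt <- filter_reviews(data$reviews, min_reviews = 100)
    scores <- suppressWarnings(rater_center_scores(filt$reviews))
    agreement <- tryCatch(
      review_panel_agreement(
        scores, panel_out$profile,
        mapping = c(overall = "appreciation", palate = "body")),
      error = function(e) NULL)
    list(filtered = filt, scores = scores, agreement = agreement)
  })

  corr_out <- .stage("correlations", {
    chem_corr <- suppressWarnings(spearman_matrix(data$chem$values))
    shared <- intersect(rownames(data$chem$values),
                        rownames(panel_out$profile$values))
    cross <- suppressWarnings(spearman_matrix(
      data$chem$values[shared, , drop = FALSE],
      panel_out$profile$values[shared, , drop = FALSE]))
    list(chem = chem_corr, cross = cross)
  })

  prep <- .stage("preprocess", {
    sp <- split_stratified(data$chem, cfg$train_frac %||% 0.7,
                           seed = stage_seed(seed, "split"))
    state <- preprocess_fit(data$chem, sp$train)
    list(split = sp, state = state,
         Xtr = preprocess_apply(state, data$chem$values[sp$train, , drop = FALSE]),
         Xte = preprocess_apply(state, data$chem$values[sp$test, , drop = FALSE]))
  })

  target_vec <- .stage("targets", {
    if ((cfg$target %||% "reviews") == "reviews") {
      sc <- reviews_out$scores
      setNames(sc$overall, sc$beer_id)
    } else {
      setNames(panel_out$profile$values[, "appreciation"],
               rownames(panel_out$profile$values))
    }
  })

  bench_out <- .stage("bench", {
    y <- target_vec[rownames(data$chem$values)]
    names(y) <- rownames(data$chem$values)
    ytr <- y[prep$split$train]; yte <- y[prep$split$test]
    models <- list()
    for (fam in (cfg$families %||% c("Lasso", "GBR", "RF"))) {
      spec <- model_spec(fam, grid = cfg$grids[[fam]],
                         seed = stage_seed(seed, "bench"))
      models[[fam]] <- fit_model(spec, prep$Xtr, ytr)
    }
    list(models = models,
         result = evaluate_suite(models, prep$Xte, yte, prep$Xtr, ytr))
  })

  dissect_out <- .stage("dissect", {
    fams <- names(bench_out$models)
    tree_fams <- intersect(c("GBR", "XGBR", "RF", "ET", "ABR"), fams)
    stop_if(length(tree_fams) == 0, "no tree family benchmarked")
    best <- tree_fams[which.max(bench_out$result$multi_output[tree_fams])]
    model <- bench_out$models[[best]]
    shap <- shapley_attributions(model, prep$Xtr)
    mdi <- mdi_ranking(model)
    y <- target_vec[prep$split$train]
    rho <- suppressWarnings(spearman_matrix(
      prep$Xtr, matrix(y, ncol = 1, dimnames = list(NULL, "target"))))
    rho_v <- setNames(rho$rho[, 1], rownames(rho$rho))
    overlap <- importance_correlation_overlap(
      shap, rho_v, k = min(15, ncol(prep$Xtr)))
    top6 <- head(shap$ranking$feature, 6)
    pdp <- lapply(top6, function(f)
      partial_dependence(model, prep$Xtr, f, grid = 20))
    names(pdp) <- top6
    list(model_family = best, model = model, shap = shap, mdi = mdi,
         overlap = overlap, pdp = pdp)
  })

  spike_out <- .stage("spike", {
    style <- cfg$spike_style %||% "Blond"
    comps <- intersect(
      head(dissect_out$shap$ranking$feature, 7),
      colnames(data$chem$values))
    in_style <- data$chem$beers$beer_id[data$chem$beers$style == style]
    if (length(in_style) < 3 || length(comps) == 0) return(NULL)
    base_id <- in_style[1]
    targets <- style_targets(data$chem, style, comps,
                             statistic = cfg$spike_statistic %||% "p95")
    plan <- spiking_plan(data$chem, base_id, targets,
                         exclude = cfg$spike_exclude %||% character(0))
    uplift <- predict_uplift(dissect_out$model, data$chem, plan, prep$state)
    list(plan = plan, uplift = uplift)
  })

  files <- c(files, .stage("artifacts", {
    f <- character(0)
    f <- c(f, .write_table(corr_long(corr_out$chem),
                           file.path(out_dir, "chem_correlations.csv")))
    f <- c(f, .write_table(corr_long(corr_out$cross, upper_only = FALSE),
                           file.path(out_dir, "chem_sensory_correlations.csv")))
    prof <- data.frame(beer_id = rownames(panel_out$profile$values),
                       panel_out$profile$values, check.names = FALSE)
    f <- c(f, .write_table(prof, file.path(out_dir, "sensory_profile.csv")))
    if (!is.null(panel_out$consistency)) {
      f <- c(f, .write_table(panel_out$consistency$table,
                             file.path(out_dir, "panel_consistency.csv")))
    }
    if (!is.null(reviews_out$agreement)) {
      f <- c(f, .write_table(reviews_out$agreement,
                             file.path(out_dir, "review_panel_agreement.csv")))
    }
    bench_df <- data.frame(model = rownames(bench_out$result$per_descriptor),
                           r2 = bench_out$result$multi_output,
                           avg_rank = bench_out$result$avg_rank,
                           train_r2 = bench_out$result$train_r2)
    f <- c(f, .write_table(bench_df, file.path(out_dir, "benchmark.csv")))
    f <- c(f, .write_table(dissect_out$mdi,
                           file.path(out_dir, "mdi_importance.csv")))
    f <- c(f, .write_table(dissect_out$shap$ranking,
                           file.path(out_dir, "shap_importance.csv")))
    shap_df <- data.frame(beer_id = rownames(dissect_out$shap$values) %||%
                            prep$split$train,
                          dissect_out$shap$values, check.names = FALSE)
    f <- c(f, .write_table(shap_df, file.path(out_dir, "shap_values.csv")))
    f <- c(f, .write_table(dissect_out$overlap$table,
                           file.path(out_dir, "importance_vs_correlation.csv")))
    pdp_long <- do.call(rbind, lapply(names(dissect_out$pdp), function(fn) {
      d <- dissect_out$pdp[[fn]]
      data.frame(feature = fn, grid = d[[1]], pd = d$pd)
    }))
    f <- c(f, .write_table(pdp_long, file.path(out_dir, "pdp_curves.csv")))
    if (!is.null(spike_out)) {
      f <- c(f, .write_table(as.data.frame(spike_out$plan),
                             file.path(out_dir, "spiking_plan.csv")))
    }
    f
  }))

  manifest <- .stage("manifest", {
    cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                                 digits = NA, null = "null")
    tmp <- file.path(out_dir, ".config.json")
    writeLines(cfg_json, tmp)
    m <- list(seed = seed,
              package_version = as.character(utils::packageVersion("flavorbench")),
              r_version = R.version.string,
              config_hash = unname(tools::md5sum(tmp)),
              files = lapply(sort(files), function(p)
                list(path = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })

  invisible(list(out_dir = out_dir, data = data, panel = panel_out,
                 reviews = reviews_out, correlations = corr_out,
                 preprocess = prep, bench = bench_out, dissect = dissect_out,
                 spike = spike_out, manifest = manifest))
}
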