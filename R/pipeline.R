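#' Default end-to-end pipeline configuration
#'
#' Demo conditions: a training cohort of 60 phantoms and a test cohort of
#' 40, strong image-immune coupling (a rim shift of three texture-noise SDs
#' per unit Th2 latent), 28 synthetic immune gene sets of 20 genes in a
#' 5000-gene universe with a 2-SD planted expression shift, and 0.632
#' bootstrap evaluation with 25 resamples of a compact margin/histogram
#' predictor panel.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param out_dir output directory for stage artifacts.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("rimmune_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cohorts = list(
      train = list(n_samples = 60L, coupling_beta = 36),
      test = list(n_samples = 40L, coupling_beta = 36)
    ),
    expression = list(n_genes = 5000L, set_size = 20L,
                      effect_size = 2, base_noise = 1),
    extraction = list(rim_depth_mm = 2, subsample_frac = 0.5, levels = 32L,
                      n_profiles = 30L, profile_len_mm = 8),
    modeling = list(
      target = "th2",
      B = 25L,
      k_neighbors = 5L,
      models = model_roster()$name,
      predictors = default_predictor_panel()
    )
  )
}

#' The default modeling predictor panel
#'
#' A compact panel of margin and histogram features: the five predictors of
#' the final linear discriminant report (total and outer-region skewness,
#' kurtosis, subsampled-delta variance, informational measure of
#' correlation) plus the delta-region mean and the margin sigmoid amplitude,
#' which carry the rim-contrast signal directly.
#'
#' @return Character vector of feature ids.
#' @export
default_predictor_panel <- function() {
  c("hist_skewness_total", "hist_skewness_outer", "hist_kurtosis_total",
    "hist_variance_deltaS", "glcm_imc1_d1",
    "hist_mean_delta", "sigmoid_amplitude_mean")
}

#' Run the full pipeline: simulate, extract, score, train, evaluate
#'
#' Executes the five stages in order with stage-scoped seeds derived from
#' the master seed: (1) simulate paired phantom/expression cohorts, (2)
#' extract the 239-feature table per cohort, (3) ssGSEA-score the immune
#' signatures and dichotomize the targets at each cohort's own mean, (4)
#' evaluate the classifier roster by the 0.632 bootstrap on the training
#' cohort and select the final model, (5) refit the final model on the
#' training cohort and evaluate it on the held-out test cohort. Writes all
#' tables as CSV under `config$out_dir` and returns a run manifest.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   to a YAML file holding one.
#' @return An object of class `run_manifest`: config hash, stage seeds,
#'   catalog census, file inventory with checksums, stage timings, and the
#'   in-memory results (`$results`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- config$seed
  timings <- list()
  files <- character(0)
  stamp <- function(name, t0) {
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
    path
  }

  # -- stage 1: simulate ----------------------------------------------------
  t0 <- Sys.time()
  gene_sets <- immune_gene_sets(config$expression$n_genes,
                                config$expression$set_size,
                                seed = derive_seed(master, "gene-sets"))
  cohorts <- purrr::imap(config$cohorts, function(cc, nm) {
    cfg <- phantom_config(
      n_samples = cc$n_samples,
      coupling_beta = cc$coupling_beta %||% 0,
      seed = derive_seed(master, paste0("cohort:", nm))
    )
    cohort <- generate_cohort(cfg)
    expr <- generate_expression(
      cohort$states, gene_sets,
      effect_size = config$expression$effect_size,
      base_noise = config$expression$base_noise,
      seed = derive_seed(master, paste0("expr:", nm))
    )
    list(name = nm, cohort = cohort, expr = expr)
  })
  stamp("simulate", t0)

  # -- stage 2: extract -----------------------------------------------------
  t0 <- Sys.time()
  catalog <- feature_catalog()
  ex <- config$extraction
  features <- purrr::map(cohorts, function(co) {
    ft <- suppressWarnings(extract_cohort(
      co$cohort$volumes, catalog = catalog,
      seed = derive_seed(master, paste0("extract:", co$name)),
      rim_depth_mm = ex$rim_depth_mm, subsample_frac = ex$subsample_frac,
      levels = ex$levels, n_profiles = ex$n_profiles,
      profile_len_mm = ex$profile_len_mm
    ))
    emit(ft, paste0("features_", co$name, ".csv"))
    ft
  })
  stamp("extract", t0)

  # -- stage 3: score + labels ----------------------------------------------
  t0 <- Sys.time()
  labels <- purrr::map(cohorts, function(co) {
    sc <- score_signatures(co$expr, gene_sets)
    emit(sc, paste0("scores_", co$name, ".csv"))
    lab <- immune_labels(sc, cohort_id = co$name)
    emit(lab, paste0("labels_", co$name, ".csv"))
    list(scores = sc, labels = lab)
  })
  stamp("score", t0)

  # -- stage 4: train -------------------------------------------------------
  t0 <- Sys.time()
  target_name <- config$modeling$target
  panel <- intersect(config$modeling$predictors, catalog$feature_id)
  get_xy <- function(which_cohort) {
    ft <- features[[which_cohort]]
    lab <- labels[[which_cohort]]$labels |>
      dplyr::filter(.data$target == target_name)
    lab <- lab[match(ft$sample_id, lab$sample_id), ]
    list(x = ft[, c("sample_id", panel)], y = lab$label)
  }
  train <- get_xy("train")
  estimates <- evaluate_models(
    train$x, train$y, models = config$modeling$models,
    B = config$modeling$B,
    seed = derive_seed(master, "boot"),
    k_neighbors = config$modeling$k_neighbors
  )
  emit(estimates, "training_estimates.csv")
  final_model <- select_final_model(estimates)
  stamp("train", t0)

  # -- stage 5: evaluate on the held-out cohort -----------------------------
  t0 <- Sys.time()
  test <- get_xy("test")
  prep <- preprocess_fit(train$x, config$modeling$k_neighbors)
  x_train <- as.matrix(preprocess_apply(prep, train$x)[, -1])
  x_test <- as.matrix(preprocess_apply(prep, test$x)[, -1])
  test_rows <- purrr::map(
    utils::head(estimates$model, 3), function(mn) {
      fit <- fit_model(mn, x_train, train$y,
                       hyper = list(seed = derive_seed(master, mn)))
      sc <- predict_scores(fit, x_test)
      ra <- roc_auc(sc, test$y)
      list(
        row = tibble::tibble(model = mn, AUC = ra$auc, p_value = ra$p_value),
        roc = dplyr::mutate(roc_points(sc, test$y), model = mn),
        final = if (mn == final_model) list(fit = fit, scores = sc) else NULL
      )
    }
  )
  if (!final_model %in% utils::head(estimates$model, 3)) {
    fit <- fit_model(final_model, x_train, train$y,
                     hyper = list(seed = derive_seed(master, final_model)))
    sc <- predict_scores(fit, x_test)
    ra <- roc_auc(sc, test$y)
    test_rows <- c(test_rows, list(list(
      row = tibble::tibble(model = final_model, AUC = ra$auc,
                           p_value = ra$p_value),
      roc = dplyr::mutate(roc_points(sc, test$y), model = final_model),
      final = list(fit = fit, scores = sc)
    )))
  }
  test_table <- dplyr::bind_rows(purrr::map(test_rows, "row"))
  emit(test_table, "test_performance.csv")
  emit(dplyr::bind_rows(purrr::map(test_rows, "roc")), "roc_points_test.csv")
  group_means <- lda_group_means(
    train$x, train$y,
    intersect(default_predictor_panel()[1:5], panel),
    config$modeling$k_neighbors
  )
  emit(group_means, "lda_group_means.csv")
  stamp("evaluate", t0)

  results <- list(
    gene_sets = gene_sets,
    states = purrr::map(cohorts, function(co) co$cohort$states),
    features = features,
    scores = purrr::map(labels, "scores"),
    labels = purrr::map(labels, "labels"),
    estimates = estimates,
    final_model = final_model,
    test_performance = test_table,
    lda_group_means = group_means
  )
  manifest <- structure(
    list(
      config_hash = digest::digest(config),
      config = config,
      seeds = list(master = master),
      census = catalog_census(),
      files = tibble::tibble(
        path = files,
        checksum = vapply(files, digest::digest, character(1), file = TRUE)
      ),
      timings = timings,
      results = results
    ),
    class = "run_manifest"
  )
  saveRDS_free_manifest(manifest, config$out_dir)
  manifest
}

# Persist a plain-text (JSON) manifest alongside the stage outputs.
saveRDS_free_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(
    list(config_hash = manifest$config_hash,
         census = as.list(manifest$census),
         files = manifest$files,
         timings = manifest$timings,
         final_model = manifest$results$final_model),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
}

validate_config <- function(config) {
  base <- default_config(seed = config$seed %||% 1L,
                         out_dir = config$out_dir %||% tempfile("rimmune_run_"))
  config <- utils::modifyList(base, config)
  stopifnot(
    is.numeric(config$seed),
    config$modeling$target %in% c("th1", "th2", "ctl"),
    config$modeling$B >= 2
  )
  config
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$config_hash, "\n")
  cat("  final model:", x$results$final_model, "\n")
  cat("  stages:", paste(sprintf("%s %.1fs", names(x$timings),
                                 unlist(x$timings)), collapse = ", "), "\n")
  cat("  files:", nrow(x$files), "artifacts in", x$config$out_dir, "\n")
  invisible(x)
}

#' Render a human-readable run summary from a manifest
#'
#' Re-reads the stage CSVs listed in the manifest and writes a single
#' plain-text report (training table, test table, LDA group means).
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param path output file (default `report.txt` in the run directory).
#' @return The report path, invisibly.
#' @export
make_report <- function(manifest, path = NULL) {
  out_dir <- manifest$config$out_dir
  path <- path %||% file.path(out_dir, "report.txt")
  fmt_tbl <- function(df) paste(utils::capture.output(print(as.data.frame(df),
                                                            row.names = FALSE)),
                                collapse = "\n")
  est <- readr::read_csv(file.path(out_dir, "training_estimates.csv"),
                         show_col_types = FALSE)
  tst <- readr::read_csv(file.path(out_dir, "test_performance.csv"),
                         show_col_types = FALSE)
  gm <- readr::read_csv(file.path(out_dir, "lda_group_means.csv"),
                        show_col_types = FALSE)
  txt <- paste0(
    "rimmune run ", manifest$config_hash, "\n",
    "target: ", manifest$config$modeling$target,
    "; final model: ", manifest$results$final_model, "\n\n",
    "Training-set 0.632 bootstrap estimates\n",
    fmt_tbl(est), "\n\n",
    "Held-out test performance\n",
    fmt_tbl(tst), "\n\n",
    "Final-model predictor group means (standardized)\n",
    fmt_tbl(gm), "\n"
  )
  writeLines(txt, path)
  invisible(path)
}
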