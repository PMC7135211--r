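#' ROC area under the curve with a rank-test p-value
#'
#' AUC by the pairwise Mann-Whitney formulation (ties count 1/2), with the
#' two-sided Mann-Whitney (Wilcoxon rank-sum) p-value for the null
#' hypothesis of no score separation (AUC = 0.5). The `high` level is the
#' positive class.
#'
#' @param scores numeric vector.
#' @param labels factor with levels `low`, `high` (or coercible).
#' @return A list with `auc` and `p_value`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_low_high(labels)
  pos <- scores[labels == "high"]
  neg <- scores[labels == "low"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("labels contain a single class; AUC undefined", call. = FALSE)
  }
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  p <- suppressWarnings(
    wilcox.test(pos, neg, alternative = "two.sided", exact = FALSE)$p.value
  )
  list(auc = auc, p_value = p)
}

as_low_high <- function(labels) {
  if (is.factor(labels) && identical(levels(labels), c("low", "high"))) {
    return(labels)
  }
  factor(as.character(labels), levels = c("low", "high"))
}

# Score cutoff maximizing Youden's J (sensitivity + specificity - 1).
youden_threshold <- function(scores, labels) {
  labels <- as_low_high(labels)
  cuts <- sort(unique(scores))
  cuts <- c(-Inf, (head(cuts, -1) + tail(cuts, -1)) / 2, Inf)
  j <- vapply(cuts, function(ct) {
    sens <- mean(scores[labels == "high"] > ct)
    spec <- mean(scores[labels == "low"] <= ct)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(j)]
}

sens_spec <- function(scores, labels, threshold) {
  labels <- as_low_high(labels)
  c(sens = mean(scores[labels == "high"] > threshold),
    spec = mean(scores[labels == "low"] <= threshold))
}

#' Evaluate one model by the 0.632 bootstrap
#'
#' For each of `B` resamples, draws n samples with replacement, refits the
#' whole preprocessing chain and the model on the resample (no leakage),
#' scores both the full training data ("apparent") and the out-of-bag
#' samples, and combines each metric as
#' `0.368 * apparent + 0.632 * out-of-bag`. Sensitivity and specificity use
#' the Youden-optimal cutoff of that resample's apparent scores.
#' Hyperparameters (when the model has a grid) are chosen inside each
#' resample by out-of-bag AUC. Reported values are the mean of the
#' per-resample combined metrics; SDs are their standard deviation.
#' Resamples whose out-of-bag set has a single class are skipped and
#' counted.
#'
#' @param name model name from [model_roster()].
#' @param table feature tibble (optionally with `sample_id`).
#' @param labels factor of `low`/`high`, one per row of `table`.
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @param k_neighbors KNN-imputation neighbours for the preprocessing chain.
#' @return A one-row tibble of class `resample_estimate`: `model`, `AUC`,
#'   `Sens`, `Spec`, `AUCSD`, `SensSD`, `SpecSD`, `B`, `B_used`, `seed`.
#' @export
bootstrap632_evaluate <- function(name, table, labels, B = 25L, seed = 1L,
                                  k_neighbors = 5L) {
  stopifnot(B >= 2L)
  labels <- as_low_high(labels)
  feat <- dplyr::select(table, -dplyr::any_of("sample_id"))
  n <- nrow(feat)
  stopifnot(length(labels) == n)
  grid <- expand_model_grid(name)

  combined <- with_seed(derive_seed(seed, paste0("boot632:", name)), {
    purrr::map(seq_len(B), function(b) {
      idx <- sample(n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) == 0L || length(unique(labels[oob])) < 2L ||
          length(unique(labels[idx])) < 2L) {
        return(NULL)
      }
      prep <- preprocess_fit(feat[idx, , drop = FALSE], k_neighbors)
      x_res <- as.matrix(preprocess_apply(prep, feat[idx, , drop = FALSE]))
      x_all <- as.matrix(preprocess_apply(prep, feat))
      y_res <- labels[idx]

      pick <- pick_hyper(name, grid, x_res, y_res, x_all[oob, , drop = FALSE],
                         labels[oob], seed = seed + b)
      fit <- pick$fit
      app_scores <- predict_scores(fit, x_all)
      oob_scores <- app_scores[oob]
      thr <- youden_threshold(app_scores, labels)
      app_auc <- roc_auc(app_scores, labels)$auc
      oob_auc <- roc_auc(oob_scores, labels[oob])$auc
      app_ss <- sens_spec(app_scores, labels, thr)
      oob_ss <- sens_spec(oob_scores, labels[oob], thr)
      c(auc = 0.368 * app_auc + 0.632 * oob_auc,
        sens = 0.368 * app_ss["sens"] + 0.632 * oob_ss["sens"],
        spec = 0.368 * app_ss["spec"] + 0.632 * oob_ss["spec"])
    })
  })
  used <- !vapply(combined, is.null, logical(1))
  if (sum(used) < 2L) {
    stop("fewer than 2 usable bootstrap resamples (single-class out-of-bag sets)",
         call. = FALSE)
  }
  m <- do.call(rbind, combined[used])
  out <- tibble::tibble(
    model = name,
    AUC = mean(m[, 1]), Sens = mean(m[, 2]), Spec = mean(m[, 3]),
    AUCSD = sd(m[, 1]), SensSD = sd(m[, 2]), SpecSD = sd(m[, 3]),
    B = as.integer(B), B_used = sum(used), seed = as.integer(seed)
  )
  class(out) <- c("resample_estimate", class(out))
  out
}

expand_model_grid <- function(name) {
  g <- model_grid(name)
  if (length(g) == 0L) return(list(list()))
  purrr::transpose(as.list(expand.grid(g)))
}

# Choose the hyperparameter combination with the best out-of-bag AUC.
pick_hyper <- function(name, grid, x_train, y_train, x_oob, y_oob, seed) {
  fits <- lapply(grid, function(h) {
    h$seed <- seed
    tryCatch(fit_model(name, x_train, y_train, h), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no hyperparameter setting could be fit for ", name,
                     call. = FALSE)
  if (sum(ok) == 1L || length(grid) == 1L) {
    return(list(fit = fits[ok][[1]]))
  }
  aucs <- vapply(fits, function(f) {
    if (is.null(f)) return(-Inf)
    roc_auc(predict_scores(f, x_oob), y_oob)$auc
  }, numeric(1))
  list(fit = fits[[which.max(aucs)]])
}

#' Evaluate the whole roster and format a training report
#'
#' Runs [bootstrap632_evaluate()] for every model and returns the rows
#' sorted by AUC, the layout of a training-set performance table
#' (AUC, Sens, Spec and their SDs per model).
#'
#' @param table feature tibble.
#' @param labels factor of `low`/`high`.
#' @param models model names (default: the full roster).
#' @param B bootstrap resamples per model.
#' @param seed RNG seed.
#' @param k_neighbors KNN-imputation neighbours.
#' @return A tibble of per-model resample estimates, AUC-descending.
#' @export
evaluate_models <- function(table, labels, models = model_roster()$name,
                            B = 25L, seed = 1L, k_neighbors = 5L) {
  rows <- purrr::map(models, function(mn) {
    bootstrap632_evaluate(mn, table, labels, B = B, seed = seed,
                          k_neighbors = k_neighbors)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$AUC))
  class(out) <- c("resample_estimate", class(out))
  out
}

#' Simplicity-aware final-model selection
#'
#' Models whose AUC is within one AUC-SD of the best model are treated as
#' statistically indistinguishable from it; among those candidates the one
#' with the smallest complexity rank wins, ties broken by roster order. This
#' is how a simpler linear model is preferred over a tree ensemble whose
#' advantage is within resampling noise.
#'
#' @param estimates tibble from [evaluate_models()] (columns `model`, `AUC`,
#'   `AUCSD`).
#' @param roster the model roster (complexity ranks and roster order).
#' @return The selected model name (length-1 character), with the candidate
#'   set as attribute `candidates`.
#' @export
select_final_model <- function(estimates, roster = model_roster()) {
  if (nrow(estimates) == 0L) stop("no estimates to select from", call. = FALSE)
  best <- estimates[which.max(estimates$AUC), ]
  window <- best$AUC - best$AUCSD
  cand <- dplyr::inner_join(estimates, roster, by = c(model = "name")) |>
    dplyr::filter(.data$AUC >= window) |>
    dplyr::arrange(.data$complexity_rank, .data$roster_order)
  sel <- cand$model[1]
  attr(sel, "candidates") <- cand$model
  sel
}

#' Standardized group means of a linear discriminant model's predictors
#'
#' Fits the preprocessing chain on the whole table, restricts to the named
#' predictors and reports the per-class (low, high) means of the
#' standardized predictors — a two-row report in the style of an LDA
#' predictor table. On centered standardized features,
#' `n_low * mean_low + n_high * mean_high = 0` per predictor.
#'
#' @param table feature tibble.
#' @param labels factor of `low`/`high`.
#' @param predictors feature ids to report.
#' @param k_neighbors KNN-imputation neighbours.
#' @return A tibble: `label` (low/high) plus one column per predictor.
#' @export
lda_group_means <- function(table, labels, predictors, k_neighbors = 5L) {
  labels <- as_low_high(labels)
  prep <- preprocess_fit(table, k_neighbors)
  missing_preds <- setdiff(predictors, prep$retained)
  if (length(missing_preds) > 0) {
    stop("predictor(s) not retained after preprocessing: ",
         paste(missing_preds, collapse = ", "), call. = FALSE)
  }
  z <- preprocess_apply(prep, table)[, predictors, drop = FALSE]
  dplyr::bind_cols(tibble::tibble(label = labels), z) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
}

#' ROC curve points for plotting
#'
#' @param scores numeric scores (higher = more `high`).
#' @param labels factor of `low`/`high`.
#' @return A tibble of (fpr, tpr) pairs sweeping the score cutoff.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_low_high(labels)
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == "high")
  fp <- cumsum(labels[ord] == "low")
  tibble::tibble(
    fpr = c(0, fp / max(1, sum(labels == "low"))),
    tpr = c(0, tp / max(1, sum(labels == "high")))
  )
}

#' Plot ROC curves for one or more models
#'
#' @param roc_tbl tibble with columns `model`, `fpr`, `tpr` (rowbound
#'   [roc_points()] outputs).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc_tbl) {
  ggplot2::ggplot(roc_tbl,
                  ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.resample_estimate <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("AUC", "Sens", "Spec"),
                        names_to = "metric", values_to = "estimate") |>
    dplyr::mutate(
      sd = dplyr::case_when(
        .data$metric == "AUC" ~ .data$AUCSD,
        .data$metric == "Sens" ~ .data$SensSD,
        TRUE ~ .data$SpecSD
      )
    ) |>
    dplyr::select("model", "metric", "estimate", "sd", "B")
}

#' @export
glance.resample_estimate <- function(x, ...) {
  tibble::tibble(
    n_models = length(unique(x$model)),
    best_model = x$model[which.max(x$AUC)],
    best_auc = max(x$AUC),
    B = x$B[1]
  )
}
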