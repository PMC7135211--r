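test_that("AUC matches the enumerated 2x2 fixture and edge cases", {
  scores <- c(0.9, 0.8, 0.7, 0.85)
  labels <- factor(c("high", "high", "low", "low"), levels = c("low", "high"))
  expect_equal(roc_auc(scores, labels)$auc, 0.75)
  # perfect separation and pure ties
  expect_equal(roc_auc(c(3, 4, 1, 2),
                       c("high", "high", "low", "low"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6),
                       rep(c("high", "low"), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("high", 3)), "single class")
})

test_that("AUC agrees with pROC and is monotone-transform invariant", {
  set.seed(21)
  scores <- rnorm(60)
  labels <- factor(ifelse(runif(60) < plogis(scores), "high", "low"),
                   levels = c("low", "high"))
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        levels = c("low", "high"),
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(roc_auc(exp(scores), labels)$auc, ours)
  expect_equal(roc_auc(scores^3, labels)$auc, ours)
  # p-value equals the two-sided Mann-Whitney test
  p_ref <- wilcox.test(scores[labels == "high"], scores[labels == "low"],
                       exact = FALSE)$p.value
  expect_equal(roc_auc(scores, labels)$p_value, p_ref)
})

test_that("Youden threshold maximizes sensitivity + specificity", {
  scores <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9)
  labels <- factor(c("low", "low", "high", "low", "high", "high"),
                   levels = c("low", "high"))
  thr <- rimmune:::youden_threshold(scores, labels)
  got <- sum(rimmune:::sens_spec(scores, labels, thr))
  brute <- max(vapply(c(-Inf, scores, Inf), function(t) {
    sum(rimmune:::sens_spec(scores, labels, t))
  }, numeric(1)))
  expect_equal(got, brute)
})

test_that("roc_points starts at (0,0), ends at (1,1) and integrates to AUC", {
  set.seed(22)
  scores <- rnorm(30)
  labels <- factor(rep(c("low", "high"), 15), levels = c("low", "high"))
  pts <- roc_points(scores, labels)
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # trapezoid integration of the step curve equals the rank AUC (no ties)
  auc_steps <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(auc_steps, roc_auc(scores, labels)$auc, tolerance = 1e-12)
  expect_s3_class(plot_roc(dplyr::mutate(pts, model = "m")), "ggplot")
})

test_that("0.632 bootstrap returns calibrated fields and honest SDs", {
  set.seed(23)
  n <- 50
  x <- tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                      f1 = rnorm(n), f2 = rnorm(n))
  y <- factor(ifelse(x$f1 + rnorm(n, sd = 0.5) > 0, "high", "low"),
              levels = c("low", "high"))
  est <- bootstrap632_evaluate("LDA", x, y, B = 10, seed = 2)
  expect_s3_class(est, "resample_estimate")
  expect_equal(est$model, "LDA")
  expect_true(est$AUC > 0.7 && est$AUC <= 1)
  expect_true(est$AUCSD >= 0 && est$SensSD >= 0 && est$SpecSD >= 0)
  expect_equal(est$B, 10L)
  expect_lte(est$B_used, 10L)
  # deterministic under the same seed, different under another
  est2 <- bootstrap632_evaluate("LDA", x, y, B = 10, seed = 2)
  expect_equal(est, est2)
  est3 <- bootstrap632_evaluate("LDA", x, y, B = 10, seed = 3)
  expect_false(isTRUE(all.equal(est$AUC, est3$AUC)))
})

test_that("evaluate_models returns the roster sorted by AUC", {
  set.seed(24)
  n <- 40
  x <- tibble::tibble(f1 = rnorm(n) + rep(c(0, 2), each = n / 2),
                      f2 = rnorm(n))
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  est <- evaluate_models(x, y, models = c("LDA", "CART", "naive_bayes"),
                         B = 6, seed = 1)
  expect_equal(nrow(est), 3L)
  expect_true(all(diff(est$AUC) <= 0))
  td <- tidy(est)
  expect_equal(nrow(td), 9L)
  gl <- glance(est)
  expect_equal(gl$n_models, 3L)
})

test_that("the selection rule prefers simplicity within one SD of the best", {
  est <- tibble::tibble(
    model = c("random_forest", "LDA", "CART"),
    AUC = c(0.795, 0.772, 0.60),
    AUCSD = c(0.108, 0.090, 0.10)
  )
  sel <- select_final_model(est)
  expect_equal(as.character(sel), "LDA")
  expect_true("random_forest" %in% attr(sel, "candidates"))
  expect_false("CART" %in% attr(sel, "candidates"))
  # a model trailing by more than one SD is not chosen
  est2 <- tibble::tibble(
    model = c("random_forest", "LDA"),
    AUC = c(0.90, 0.70), AUCSD = c(0.05, 0.05)
  )
  expect_equal(as.character(select_final_model(est2)), "random_forest")
  # ties inside the window break toward the lower complexity rank
  est3 <- tibble::tibble(
    model = c("penalized_DA", "penalized_logistic"),
    AUC = c(0.80, 0.80), AUCSD = c(0.05, 0.05)
  )
  expect_equal(as.character(select_final_model(est3)), "penalized_DA")
})

test_that("lda_group_means is a balanced two-row standardized report", {
  set.seed(25)
  n <- 30
  tbl <- tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                        a = rnorm(n) + rep(c(0, 1), each = n / 2),
                        b = rexp(n))
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  gm <- lda_group_means(tbl, y, predictors = c("a", "b"))
  expect_equal(nrow(gm), 2L)
  expect_setequal(as.character(gm$label), c("low", "high"))
  # standardized + balanced classes: group means cancel per predictor
  expect_lt(abs(sum(gm$a)), 1e-8)
  expect_lt(abs(sum(gm$b)), 1e-8)
  expect_gt(gm$a[gm$label == "high"], gm$a[gm$label == "low"])
  expect_error(lda_group_means(tbl, y, predictors = "missing_feature"),
               "not retained")
})

test_that("hyperparameter grids expand to lists of combinations", {
  g <- rimmune:::expand_model_grid("penalized_logistic")
  expect_length(g, 3L)
  expect_equal(rimmune:::expand_model_grid("LDA"), list(list()))
})
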