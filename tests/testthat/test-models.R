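sep_data <- function(n = 40, gap = 3, seed = 1, p = 2) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[y == "high", 1] <- x[y == "high", 1] + gap
  list(x = x, y = y)
}

test_that("the roster has eight models with sane complexity ranks", {
  r <- model_roster()
  expect_equal(nrow(r), 8L)
  expect_setequal(r$complexity_rank, 1:8)
  # the plain linear discriminant is the simplest model
  expect_equal(r$name[r$complexity_rank == 1], "LDA")
  # tree ensembles are the most complex
  expect_gt(r$complexity_rank[r$name == "random_forest"],
            r$complexity_rank[r$name == "LDA"])
  expect_gt(r$complexity_rank[r$name == "bagged_CART"],
            r$complexity_rank[r$name == "CART"])
})

test_that("every roster model fits and separates an easy problem", {
  d <- sep_data(n = 40, gap = 4)
  for (mn in model_roster()$name) {
    fit <- fit_model(mn, d$x, d$y, hyper = list(seed = 1L))
    sc <- predict_scores(fit, d$x)
    expect_length(sc, 40)
    expect_equal(roc_auc(sc, d$y)$auc, 1,
                 tolerance = 0.051, label = paste("AUC of", mn))
  }
})

test_that("closed-form LDA matches MASS::lda decisions and direction", {
  d <- sep_data(n = 60, gap = 2, seed = 2, p = 3)
  ours <- fit_model("LDA", d$x, d$y)
  sc <- predict_scores(ours, d$x)
  ref <- MASS::lda(d$x, grouping = d$y)
  post <- predict(ref, d$x)$posterior[, "high"]
  # identical ranking of samples
  expect_equal(order(sc), order(post))
  # our score is the log posterior odds of `high`
  expect_equal(sc, log(post / (1 - post)), tolerance = 1e-8)
  # discriminant direction proportional to MASS's scaling
  w <- ours$fit$w
  expect_gt(abs(cor(w, ref$scaling[, 1])), 1 - 1e-8)
})

test_that("closed-form naive Bayes matches e1071 posteriors in rank", {
  d <- sep_data(n = 50, gap = 2, seed = 3, p = 3)
  ours <- fit_model("naive_bayes", d$x, d$y)
  sc <- predict_scores(ours, d$x)
  ref <- e1071::naiveBayes(d$x, d$y)
  post <- predict(ref, d$x, type = "raw")[, "high"]
  expect_equal(order(sc), order(post))
  # e1071 uses 1/(n-1) variances; ours are the same, so the log odds agree
  expect_equal(sc, log(post) - log(1 - post), tolerance = 1e-6)
})

test_that("LDA decision boundary sits midway between balanced classes", {
  x <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- factor(c("low", "low", "low", "high", "high", "high"),
              levels = c("low", "high"))
  fit <- fit_model("LDA", x, y)
  mid <- matrix(0, 1, 1, dimnames = list(NULL, "f1"))
  expect_lt(abs(predict_scores(fit, mid)), 1e-8)
  expect_lt(predict_scores(fit, mid - 0.5), 0)
  expect_gt(predict_scores(fit, mid + 0.5), 0)
})

test_that("penalized DA shrinks the covariance and survives p > n", {
  d <- sep_data(n = 12, gap = 2, seed = 4, p = 20)  # singular pooled cov
  expect_message(fit0 <- fit_model("LDA", d$x, d$y), "ridge")
  fit <- fit_model("penalized_DA", d$x, d$y, hyper = list(gamma = 0.5))
  sc <- predict_scores(fit, d$x)
  expect_true(all(is.finite(sc)))
  # gamma = 0 equals plain LDA
  d2 <- sep_data(n = 40, gap = 2, seed = 5, p = 3)
  f_lda <- fit_model("LDA", d2$x, d2$y)
  f_pda0 <- rimmune:::fit_gaussian_lda(d2$x, d2$y, gamma = 0)
  expect_equal(f_lda$fit$w, f_pda0$w)
})

test_that("sparse DA zeroes out noise features at adequate lambda", {
  d <- sep_data(n = 60, gap = 3, seed = 6, p = 6)  # only f1 informative
  fit <- fit_model("sparse_DA", d$x, d$y, hyper = list(lambda = 0.05))
  beta <- fit$fit$beta
  expect_gt(abs(beta[["f1"]]), 0)
  expect_gt(sum(abs(beta[-1]) < 1e-8), 0)  # some noise features dropped
  # orientation: high class scores higher
  sc <- predict_scores(fit, d$x)
  expect_gt(mean(sc[d$y == "high"]), mean(sc[d$y == "low"]))
})

test_that("tree models are seeded and deterministic", {
  d <- sep_data(n = 40, gap = 1, seed = 7, p = 4)
  for (mn in c("bagged_CART", "random_forest")) {
    s1 <- predict_scores(fit_model(mn, d$x, d$y, list(seed = 3L)), d$x)
    s2 <- predict_scores(fit_model(mn, d$x, d$y, list(seed = 3L)), d$x)
    expect_identical(s1, s2)
  }
})

test_that("single-class training data is rejected", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep("low", 5), levels = c("low", "high"))
  expect_error(fit_model("LDA", x, y), "single class")
  expect_error(fit_model("made_up", x, factor(c("low", "high", "low", "high",
                                                "low"),
                                              levels = c("low", "high"))),
               "unknown model")
})
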