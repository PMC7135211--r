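test_that("Yeo-Johnson matches its closed-form branches", {
  x <- c(-3, -1.5, 0, 0.5, 2, 10)
  # lambda = 1 is the identity on all reals
  expect_equal(yeo_johnson(x, 1), x, tolerance = 1e-12)
  # lambda = 0: log branch for non-negatives
  expect_equal(yeo_johnson(3, 0), log(4), tolerance = 1e-12)
  expect_equal(yeo_johnson(0, 0), 0)
  # lambda = 2: negative branch becomes -log1p(-x)
  expect_equal(yeo_johnson(-2, 2), -log(3), tolerance = 1e-12)
  # generic branches
  expect_equal(yeo_johnson(3, 0.5), ((4)^0.5 - 1) / 0.5, tolerance = 1e-12)
  expect_equal(yeo_johnson(-2, 0.5), -((3)^1.5 - 1) / 1.5, tolerance = 1e-12)
  # continuity across lambda at the branch points
  expect_equal(yeo_johnson(5, 1e-9), yeo_johnson(5, 0), tolerance = 1e-6)
  # monotone increasing in x for any lambda
  for (l in c(-1, 0, 0.5, 1, 2, 2.5)) {
    expect_true(all(diff(yeo_johnson(sort(x), l)) > 0))
  }
  expect_equal(yeo_johnson(c(1, NA), 1), c(1, NA))
})

test_that("ML lambda reduces skewness of a skewed sample", {
  set.seed(11)
  x <- exp(rnorm(300))  # strongly right-skewed
  l <- yeo_johnson_lambda(x)
  expect_lt(l, 1)  # right skew calls for a contracting transform
  sk <- function(v) mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5
  expect_lt(abs(sk(yeo_johnson(x, l))), abs(sk(x)) / 2)
  # constant input falls back to the identity lambda
  expect_equal(yeo_johnson_lambda(rep(4, 10)), 1)
})

test_that("our transform agrees with caret's Yeo-Johnson on shared data", {
  set.seed(12)
  df <- data.frame(f = exp(rnorm(150)))
  pp <- caret::preProcess(df, method = "YeoJohnson")
  ours <- yeo_johnson(df$f, yeo_johnson_lambda(df$f))
  theirs <- predict(pp, df)$f
  # both estimate lambda by ML; transformed samples should be nearly
  # identical up to optimizer tolerance
  expect_gt(cor(ours, theirs), 0.9999)
})

test_that("the chain removes zero-variance features and standardizes", {
  set.seed(13)
  tbl <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:30),
    good1 = rnorm(30), good2 = rexp(30), flat = rep(3, 30)
  )
  prep <- preprocess_fit(tbl, k_neighbors = 3)
  expect_setequal(prep$retained, c("good1", "good2"))
  z <- preprocess_apply(prep, tbl)
  expect_identical(names(z), c("sample_id", "good1", "good2"))
  expect_lt(abs(mean(z$good1)), 1e-8)
  expect_equal(sd(z$good1), 1, tolerance = 1e-8)
  expect_lt(abs(mean(z$good2)), 1e-8)
  expect_equal(sd(z$good2), 1, tolerance = 1e-8)
})

test_that("KNN imputation fills missings from the nearest donors", {
  # two tight clusters; the missing value must come from the same cluster
  tbl <- tibble::tibble(
    a = c(0, 0.1, 0.2, 10, 10.1, 10.2),
    b = c(1, 1.1, 0.9, 5, 5.2, 4.8),
    c = c(2, 2.1, NA, 7, 6.9, 7.1)
  )
  imp <- rimmune:::knn_impute(tbl, tbl, k = 2)
  expect_equal(imp$c[3], mean(c(2, 2.1)), tolerance = 1e-12)
  # k = 1: the value of the single nearest row
  imp1 <- rimmune:::knn_impute(tbl, tbl, k = 1)
  expect_true(imp1$c[3] %in% c(2, 2.1))
  # all-missing feature in the query falls back to the reference mean
  q <- tibble::tibble(a = 0.15, b = NA_real_, c = NA_real_)
  ref <- tbl[!is.na(tbl$c), ]
  imp2 <- rimmune:::knn_impute(q, ref, k = 2)
  expect_true(is.finite(imp2$b) && is.finite(imp2$c))
})

test_that("applying a fitted chain to new data uses training statistics", {
  set.seed(14)
  train <- tibble::tibble(x = rnorm(40, 10, 2), y = rexp(40))
  test <- tibble::tibble(x = rnorm(15, 10, 2), y = rexp(15))
  prep <- preprocess_fit(train)
  z_test <- preprocess_apply(prep, test)
  # transforming the training data itself is standardized ...
  z_train <- preprocess_apply(prep, train)
  expect_lt(abs(mean(z_train$x)), 1e-8)
  # ... but held-out data is not exactly, proving train-only statistics
  expect_gt(abs(mean(z_test$x)), 1e-8)
  # no leakage: refitting on a subset changes the statistics
  prep_sub <- preprocess_fit(train[1:20, ])
  expect_false(isTRUE(all.equal(prep$centers, prep_sub$centers)))
})

test_that("imputation happens before the transform and standardization", {
  tbl <- tibble::tibble(a = c(1, 2, 3, 4, NA), b = c(2, 3, 4, 5, 6))
  prep <- preprocess_fit(tbl, k_neighbors = 2)
  z <- preprocess_apply(prep, tbl)
  expect_false(anyNA(z))
  expect_lt(abs(mean(z$a)), 1e-8)
})
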