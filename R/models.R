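#' The classifier roster
#'
#' The eight model families used for high/low immune-status prediction, in
#' roster order, with complexity ranks: plain discriminants are simplest,
#' then penalized linear models, naive Bayes, a single tree, and tree
#' ensembles. Ranks drive the simplicity-aware final-model selection.
#'
#' @return A tibble: `name`, `label`, `complexity_rank`, `roster_order`.
#' @export
model_roster <- function() {
  tibble::tibble(
    name = c("penalized_logistic", "penalized_DA", "sparse_DA", "LDA",
             "naive_bayes", "CART", "bagged_CART", "random_forest"),
    label = c("Penalized logistic regression", "Penalized discriminant analysis",
              "Sparse discriminant analysis", "Linear discriminant",
              "Naive Bayes", "CART", "Bagged CART", "Random forest"),
    complexity_rank = c(3L, 2L, 4L, 1L, 5L, 6L, 7L, 8L),
    roster_order = 1:8
  )
}

# Fixed hyperparameter grids, searched inside each resample by out-of-bag
# AUC; an empty list means the model has no tunable.
model_grid <- function(name) {
  switch(name,
    penalized_logistic = list(lambda = c(0.01, 0.1, 1)),
    penalized_DA = list(gamma = c(0.2, 0.5, 0.8)),
    sparse_DA = list(lambda = c(0.01, 0.05, 0.1)),
    CART = list(cp = c(0.01, 0.05)),
    list()
  )
}

#' Fit one classifier
#'
#' All models share one interface: `fit_model()` takes a numeric feature
#' matrix and a two-level factor (`low`, `high`), [predict_scores()] returns
#' a continuous score oriented so larger means more likely `high`. LDA and
#' naive Bayes are computed from their closed-form Gaussian definitions;
#' penalized logistic regression and sparse discriminant analysis (lasso
#' optimal scoring) use glmnet; penalized discriminant analysis is LDA with
#' the pooled covariance shrunk toward its diagonal; CART/bagged CART use
#' rpart; random forest uses ranger.
#'
#' @param name model name from [model_roster()].
#' @param x numeric matrix (samples x features).
#' @param y factor with levels `low`, `high`.
#' @param hyper named list of hyperparameters (see `model_grid`).
#' @return A fitted model object of class `rimmune_model`.
#' @export
fit_model <- function(name, x, y, hyper = list()) {
  stopifnot(is.matrix(x), is.factor(y), nlevels(y) == 2L)
  if (length(unique(y)) < 2L) stop("training data has a single class", call. = FALSE)
  fit <- switch(name,
    LDA = fit_gaussian_lda(x, y, gamma = 0),
    penalized_DA = fit_gaussian_lda(x, y, gamma = hyper$gamma %||% 0.5),
    naive_bayes = fit_gaussian_nb(x, y),
    penalized_logistic = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0,
      lambda = hyper$lambda %||% 0.1
    ),
    sparse_DA = fit_sparse_da(x, y, lambda = hyper$lambda %||% 0.05),
    CART = rpart::rpart(
      y ~ ., data = data.frame(y = y, x, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(cp = hyper$cp %||% 0.01, minsplit = 10)
    ),
    bagged_CART = fit_bagged_cart(x, y, n_trees = hyper$n_trees %||% 25L,
                                  seed = hyper$seed %||% 1L),
    random_forest = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = hyper$num_trees %||% 300L,
      seed = hyper$seed %||% 1L, num.threads = 1L
    ),
    stop("unknown model: ", name, call. = FALSE)
  )
  structure(list(name = name, fit = fit, hyper = hyper,
                 feature_names = colnames(x)),
            class = "rimmune_model")
}

#' @rdname fit_model
#' @param model a fitted `rimmune_model`.
#' @param newx numeric matrix of features.
#' @return `predict_scores()`: numeric vector, higher = more likely `high`.
#' @export
predict_scores <- function(model, newx) {
  stopifnot(inherits(model, "rimmune_model"))
  newx <- newx[, model$feature_names, drop = FALSE]
  fit <- model$fit
  switch(model$name,
    LDA = ,
    penalized_DA = predict_gaussian_lda(fit, newx),
    naive_bayes = predict_gaussian_nb(fit, newx),
    penalized_logistic = as.numeric(
      predict(fit, newx, type = "link")[, 1]
    ),
    sparse_DA = as.numeric(newx %*% fit$beta + fit$intercept),
    CART = predict(fit, data.frame(newx, check.names = FALSE))[, "high"],
    bagged_CART = predict_bagged_cart(fit, newx),
    random_forest = predict(fit, data = newx, num.threads = 1L)$predictions[, "high"]
  )
}

# --- closed-form Gaussian discriminants -----------------------------------

# Shared-covariance Gaussian discriminant. gamma in [0, 1) shrinks the
# pooled covariance toward its diagonal (penalized DA); a ridge epsilon is
# added automatically (and noted) when the matrix is singular.
fit_gaussian_lda <- function(x, y, gamma = 0) {
  classes <- levels(y)
  mus <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  n <- nrow(x)
  centered <- x - do.call(rbind, lapply(seq_len(n), function(i) {
    mus[[as.integer(y[i])]]
  }))
  sigma <- crossprod(centered) / max(1, n - length(classes))
  if (gamma > 0) {
    sigma <- (1 - gamma) * sigma + gamma * diag(diag(sigma), ncol(x))
  }
  ridge_used <- 0
  w <- tryCatch(solve(sigma, mus[[2]] - mus[[1]]), error = function(e) NULL)
  if (is.null(w)) {
    ridge_used <- 1e-6 * mean(diag(sigma))
    message(sprintf("singular pooled covariance; ridge epsilon %.3g added",
                    ridge_used))
    w <- solve(sigma + diag(ridge_used, ncol(x)), mus[[2]] - mus[[1]])
  }
  priors <- table(y) / n
  b <- log(priors[[2]] / priors[[1]]) -
    0.5 * sum((mus[[2]] + mus[[1]]) * w)
  list(w = as.numeric(w), b = b, mus = mus, sigma = sigma,
       ridge = ridge_used, classes = classes)
}

predict_gaussian_lda <- function(fit, newx) {
  as.numeric(newx %*% fit$w + fit$b)
}

# Per-class independent Gaussians; returns log posterior odds of `high`.
fit_gaussian_nb <- function(x, y) {
  classes <- levels(y)
  stats_by_class <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    v <- apply(xc, 2, var)
    floor_v <- 1e-9 * max(1, mean(v[is.finite(v)], na.rm = TRUE))
    list(mu = colMeans(xc), var = pmax(v, floor_v))
  })
  names(stats_by_class) <- classes
  list(stats = stats_by_class, log_priors = log(table(y) / length(y)),
       classes = classes)
}

predict_gaussian_nb <- function(fit, newx) {
  ll <- vapply(fit$classes, function(cl) {
    st <- fit$stats[[cl]]
    rowSums(
      -0.5 * log(2 * pi * matrix(st$var, nrow(newx), ncol(newx), byrow = TRUE)) -
        0.5 * sweep(newx, 2, st$mu)^2 /
          matrix(st$var, nrow(newx), ncol(newx), byrow = TRUE)
    ) + fit$log_priors[[cl]]
  }, numeric(nrow(newx)))
  ll <- matrix(ll, ncol = 2)
  ll[, 2] - ll[, 1]
}

# Sparse discriminant analysis via lasso optimal scoring: for two classes
# the discriminant direction solves a lasso regression of the class scores.
fit_sparse_da <- function(x, y, lambda) {
  n <- length(y)
  n1 <- sum(y == levels(y)[2]); n0 <- n - n1
  z <- ifelse(y == levels(y)[2], sqrt(n0 / (n1 * n)), -sqrt(n1 / (n0 * n)))
  g <- glmnet::glmnet(x, z, family = "gaussian", alpha = 1, lambda = lambda)
  beta <- as.numeric(g$beta)
  names(beta) <- colnames(x)
  # orient so the `high` class scores higher
  proj <- as.numeric(x %*% beta)
  if (mean(proj[y == levels(y)[2]]) < mean(proj[y == levels(y)[1]])) {
    beta <- -beta
  }
  list(beta = beta, intercept = -mean(x %*% beta))
}

fit_bagged_cart <- function(x, y, n_trees, seed) {
  df <- data.frame(y = y, x, check.names = FALSE)
  with_seed(derive_seed(seed, "bagged-cart"), {
    trees <- lapply(seq_len(n_trees), function(t) {
      idx <- sample(nrow(df), replace = TRUE)
      if (length(unique(df$y[idx])) < 2L) idx <- seq_len(nrow(df))
      rpart::rpart(y ~ ., data = df[idx, ], method = "class",
                   control = rpart::rpart.control(cp = 0.01, minsplit = 10))
    })
    list(trees = trees)
  })
}

predict_bagged_cart <- function(fit, newx) {
  df <- data.frame(newx, check.names = FALSE)
  probs <- vapply(fit$trees, function(tr) predict(tr, df)[, "high"],
                  numeric(nrow(df)))
  rowMeans(matrix(probs, nrow = nrow(df)))
}
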