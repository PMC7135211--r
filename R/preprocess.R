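#' Yeo-Johnson power transform
#'
#' Defined on all reals: for `x >= 0`, `((x+1)^lambda - 1)/lambda`
#' (`log(x+1)` at `lambda = 0`); for `x < 0`,
#' `-((-x+1)^(2-lambda) - 1)/(2-lambda)` (`-log(-x+1)` at `lambda = 2`).
#' `lambda = 1` is the identity.
#'
#' @param x numeric vector.
#' @param lambda transform parameter.
#' @return Transformed vector of the same length.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Maximum-likelihood Yeo-Johnson lambda
#'
#' Profiles the Gaussian log-likelihood of the transformed sample (with the
#' log-Jacobian `(lambda - 1) * sum(sign(x) * log(|x| + 1))`) over a lambda
#' interval.
#'
#' @param x numeric vector (NAs dropped).
#' @param interval search interval for lambda.
#' @return The maximizing lambda (1 for constant input).
#' @export
yeo_johnson_lambda <- function(x, interval = c(-2, 3)) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || var(x) == 0) return(1)
  jac <- sum(sign(x) * log1p(abs(x)))
  negloglik <- function(l) {
    z <- yeo_johnson(x, l)
    s2 <- pop_moment(z, 2)
    if (!is.finite(s2) || s2 <= 0) return(Inf)
    length(x) / 2 * log(s2) - (l - 1) * jac
  }
  optimize(negloglik, interval)$minimum
}

#' Fit the preprocessing chain on a feature table
#'
#' Stages, in order: remove zero-variance features, KNN-impute missing
#' values (Euclidean distance over shared features, computed on
#' per-feature standardized values), resolve skewness per feature by a
#' maximum-likelihood Yeo-Johnson transform, then center and scale to
#' z-scores. Statistics are estimated only from the rows given here, so the
#' chain can be refit inside each resample without leakage.
#'
#' @param table tibble or data.frame with a `sample_id` column (optional)
#'   and numeric feature columns.
#' @param k_neighbors neighbours for KNN imputation.
#' @return An object of class `preprocessor`: retained feature ids, the
#'   imputation training data, per-feature lambda, center and scale.
#' @export
preprocess_fit <- function(table, k_neighbors = 5L) {
  x <- as.data.frame(dplyr::select(table, -dplyr::any_of("sample_id")))
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  variances <- vapply(x, function(col) var(col, na.rm = TRUE), numeric(1))
  retained <- names(x)[is.finite(variances) & variances > 0]
  if (length(retained) == 0L) stop("all features have zero variance", call. = FALSE)
  x <- x[, retained, drop = FALSE]

  imputed <- knn_impute(x, x, k_neighbors)
  lambdas <- vapply(imputed, yeo_johnson_lambda, numeric(1))
  transformed <- as.data.frame(
    purrr::imap(imputed, function(col, nm) yeo_johnson(col, lambdas[[nm]]))
  )
  centers <- vapply(transformed, mean, numeric(1))
  scales <- vapply(transformed, sd, numeric(1))
  scales[scales == 0 | !is.finite(scales)] <- 1
  structure(
    list(retained = retained, k_neighbors = as.integer(k_neighbors),
         impute_reference = x, lambdas = lambdas,
         centers = centers, scales = scales),
    class = "preprocessor"
  )
}

#' @rdname preprocess_fit
#' @param state a fitted `preprocessor`.
#' @param new_table feature table to transform.
#' @return `preprocess_apply()`: tibble of transformed features (plus
#'   `sample_id` if present in the input).
#' @export
preprocess_apply <- function(state, new_table) {
  stopifnot(inherits(state, "preprocessor"))
  ids <- if ("sample_id" %in% names(new_table)) new_table$sample_id else NULL
  x <- as.data.frame(new_table)[, state$retained, drop = FALSE]
  x <- knn_impute(x, state$impute_reference, state$k_neighbors)
  out <- purrr::imap(x, function(col, nm) {
    (yeo_johnson(col, state$lambdas[[nm]]) - state$centers[[nm]]) /
      state$scales[[nm]]
  })
  out <- tibble::as_tibble(out)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
  out
}

# KNN imputation: each missing cell takes the mean of that feature over the
# k nearest reference rows, with distances computed on the features observed
# in both rows (standardized by the reference SDs). Falls back to the
# reference feature mean when no usable neighbour exists.
knn_impute <- function(x, reference, k) {
  if (!anyNA(x)) return(x)
  ref <- as.matrix(reference)
  qry <- as.matrix(x)
  mu <- colMeans(ref, na.rm = TRUE)
  sg <- apply(ref, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  refs <- sweep(sweep(ref, 2, mu), 2, sg, `/`)
  qrys <- sweep(sweep(qry, 2, mu), 2, sg, `/`)
  for (row in which(!complete.cases(qry))) {
    miss <- which(is.na(qry[row, ]))
    obs <- which(!is.na(qry[row, ]))
    for (col in miss) {
      # rows missing this feature (incl. the query row itself when imputing
      # the training data in place) can never donate a value
      cand <- which(!is.na(ref[, col]))
      if (length(obs) == 0L || length(cand) == 0L) {
        qry[row, col] <- mu[col]
        next
      }
      diffs <- refs[cand, obs, drop = FALSE] -
        matrix(qrys[row, obs], length(cand), length(obs), byrow = TRUE)
      d2 <- rowMeans(diffs^2, na.rm = TRUE)
      d2[!is.finite(d2)] <- Inf
      nn <- cand[order(d2)[seq_len(min(k, length(cand)))]]
      qry[row, col] <- mean(ref[nn, col], na.rm = TRUE)
    }
  }
  as.data.frame(qry)
}
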