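#' Single-sample gene-set enrichment score
#'
#' Rank-based per-sample enrichment score in the Barbie (ssGSEA) style:
#' genes are ranked by expression (descending, ties broken by stable gene
#' order), the ranked list is walked from the top accumulating the weighted
#' in-set empirical distribution (weight `rank^alpha`, normalized over the
#' set) minus the uniform out-of-set distribution, and the score is the sum
#' of the running differences (the integrated enrichment statistic).
#' With `alpha = 0` the score depends on ranks only, so it is invariant
#' under any strictly monotone transform of the expression values.
#'
#' @param sample_expression named numeric vector (gene -> expression) for
#'   one sample.
#' @param gene_set character vector of gene ids; must intersect the
#'   expressed genes and must not cover all of them.
#' @param alpha rank-weighting exponent (0.25 by default).
#' @return A single numeric enrichment score, or `NA` (with a warning) when
#'   the set does not intersect the expressed genes.
#' @export
ssgsea_score <- function(sample_expression, gene_set, alpha = 0.25) {
  genes <- names(sample_expression)
  n <- length(genes)
  in_set_genes <- intersect(gene_set, genes)
  if (length(in_set_genes) == 0L) {
    warning("gene set has no overlap with expressed genes; score is NA",
            call. = FALSE)
    return(NA_real_)
  }
  if (length(in_set_genes) >= n) {
    stop("gene set covers every expressed gene; out-of-set walk undefined",
         call. = FALSE)
  }
  # descending expression, ties by original gene order (stable)
  ord <- order(-sample_expression, seq_len(n))
  in_set <- genes[ord] %in% in_set_genes
  # rank value: top gene has rank n
  r <- as.numeric(n:1)
  w_in <- ifelse(in_set, r^alpha, 0)
  denom_in <- sum(w_in)
  p_in <- cumsum(w_in) / denom_in
  p_out <- cumsum(!in_set) / (n - length(in_set_genes))
  sum(p_in - p_out)
}

#' Score every sample against every gene set
#'
#' Applies [ssgsea_score()] per sample and set; with `normalize = TRUE` all
#' scores are divided by the global range (max - min across the whole
#' matrix), the usual ssGSEA normalization.
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param sets named list of gene sets.
#' @param alpha rank-weighting exponent.
#' @param normalize divide by the global score range.
#' @return A tibble: `sample_id` plus one column per gene set, with
#'   attribute `normalized`.
#' @export
score_signatures <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(names(sets))) stop("gene set names must be unique", call. = FALSE)
  scores <- vapply(seq_len(ncol(expr)), function(si) {
    sample_expr <- expr[, si]
    vapply(sets, function(gs) ssgsea_score(sample_expr, gs, alpha), numeric(1))
  }, numeric(length(sets)))
  scores <- t(matrix(scores, nrow = length(sets),
                     dimnames = list(names(sets), colnames(expr))))
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    span <- rng[2] - rng[1]
    if (span > 0) scores <- scores / span
  }
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(expr)),
    tibble::as_tibble(scores)
  )
  attr(out, "normalized") <- normalize
  out
}

#' Principal component analysis of signature scores
#'
#' Column-centred (covariance) PCA of the samples-by-signatures score
#' matrix. The sign convention makes each component's largest-magnitude
#' loading positive.
#'
#' @param score_tbl tibble from [score_signatures()] (`sample_id` + one
#'   column per signature).
#' @param k number of components to keep (truncated to the matrix rank,
#'   with a warning).
#' @return An object of class `signature_pca`: list with `loadings`
#'   (signatures x k), `scores` (samples x k), `explained_variance`
#'   (fractions), `sample_ids`.
#' @export
pca_signatures <- function(score_tbl, k = 2L) {
  m <- as.matrix(dplyr::select(score_tbl, -"sample_id"))
  rownames(m) <- score_tbl$sample_id
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncating", k, rank),
            call. = FALSE)
    k <- rank
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scor <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (cc in seq_len(k)) {
    peak <- which.max(abs(load[, cc]))
    if (load[peak, cc] < 0) {
      load[, cc] <- -load[, cc]
      scor[, cc] <- -scor[, cc]
    }
  }
  structure(
    list(loadings = load, scores = scor,
         explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
         sample_ids = score_tbl$sample_id),
    class = "signature_pca"
  )
}

#' @export
print.signature_pca <- function(x, ...) {
  cat(sprintf("<signature_pca> %d signatures, %d samples, %d components\n",
              nrow(x$loadings), nrow(x$scores), ncol(x$loadings)))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.signature_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "signature") |>
    tidyr::pivot_longer(-"signature", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.signature_pca <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$loadings),
    n_signatures = nrow(x$loadings),
    n_samples = nrow(x$scores),
    var_explained_total = sum(x$explained_variance)
  )
}

#' @export
autoplot.signature_pca <- function(object, ...) {
  df <- tibble::as_tibble(object$scores, rownames = "sample_id")
  cols <- colnames(object$scores)[1:2]
  ggplot2::ggplot(df, ggplot2::aes(.data[[cols[1]]], .data[[cols[2]]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", cols[1], 100 * object$explained_variance[1]),
      y = sprintf("%s (%.1f%%)", cols[2], 100 * object$explained_variance[2]),
      title = "PCA of immune signature scores"
    ) +
    ggplot2::theme_minimal()
}

#' Dichotomize signature scores at the cohort mean
#'
#' Labels a sample `high` iff its score exceeds the mean score of its own
#' cohort; each cohort always uses its own cutoff, never a pooled one.
#'
#' @param scores numeric vector of per-sample scores.
#' @param sample_ids sample identifiers (defaults to names of `scores`).
#' @param cohort_id cohort identifier recorded alongside the cutoff.
#' @param target name of the signature being dichotomized.
#' @return A tibble: `sample_id`, `target`, `label` (`high`/`low`),
#'   `cutoff`, `cohort`.
#' @export
dichotomize <- function(scores, sample_ids = names(scores),
                        cohort_id = "cohort", target = "signature") {
  if (length(unique(scores)) == 1L) {
    stop("all scores identical: degenerate split at the mean", call. = FALSE)
  }
  cutoff <- mean(scores)
  tibble::tibble(
    sample_id = sample_ids %||% as.character(seq_along(scores)),
    target = target,
    label = factor(ifelse(scores > cutoff, "high", "low"),
                   levels = c("low", "high")),
    cutoff = cutoff,
    cohort = cohort_id
  )
}

#' High/low immune labels for the designated targets
#'
#' @param score_tbl tibble from [score_signatures()].
#' @param targets named character vector mapping short target names to
#'   signature columns.
#' @param cohort_id cohort identifier (cutoffs are always per cohort).
#' @return A tibble with one row per sample and target.
#' @export
immune_labels <- function(score_tbl,
                          targets = c(th1 = "Th1 cells", th2 = "Th2 cells",
                                      ctl = "Cytotoxic cells"),
                          cohort_id = "cohort") {
  missing_cols <- setdiff(unname(targets), colnames(score_tbl))
  if (length(missing_cols) > 0) {
    stop("score table lacks signature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  purrr::imap(targets, function(col, short) {
    dichotomize(score_tbl[[col]], score_tbl$sample_id,
                cohort_id = cohort_id, target = short)
  }) |>
    dplyr::bind_rows()
}
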