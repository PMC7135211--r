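#' First-order (histogram) statistics of an intensity sample
#'
#' Computes the eleven per-region histogram statistics of the catalog:
#' mean, SD, variance, skewness, excess kurtosis, median, min, max, entropy,
#' uniformity and interquartile range. Moments use population (1/n)
#' definitions: variance `m2 = mean((x - mean)^2)`, skewness `m3 / m2^1.5`,
#' kurtosis reported as excess, `m4 / m2^2 - 3`. Entropy and uniformity are
#' computed on an equal-width discretization of the sample range.
#'
#' @param values numeric vector of intensities (at least 2).
#' @param n_bins bins for the entropy/uniformity discretization.
#' @return Named numeric vector; for a zero-variance sample, skewness and
#'   kurtosis are `NA` (imputed downstream) and entropy/uniformity use the
#'   single-bin convention.
#' @export
histogram_features <- function(values, n_bins = 32L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("histogram features need at least 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  m2 <- pop_moment(values, 2)
  if (m2 > 0) {
    skew <- pop_moment(values, 3) / m2^1.5
    kurt <- pop_moment(values, 4) / m2^2 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  p <- bin_probabilities(values, n_bins)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = m,
    sd = sqrt(m2),
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    median = median(values),
    min = min(values),
    max = max(values),
    entropy = -sum(p[p > 0] * log2(p[p > 0])),
    uniformity = sum(p^2),
    iqr = q[2] - q[1])
}

# Equal-width bin probabilities over the sample range; a constant sample is
# a single-bin point mass.
bin_probabilities <- function(values, n_bins) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(1)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  counts / sum(counts)
}

# Percentile features (type-7 quantiles) on the total region.
percentile_features <- function(values, probs = c(0.10, 0.25, 0.75, 0.90)) {
  q <- quantile(values, probs, names = FALSE, type = 7)
  setNames(q, paste0("p", round(probs * 100)))
}

# Discretize intensities to 1..levels with equal-width bins over min-max.
# A constant sample maps to a single level.
discretize_intensities <- function(values, levels) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  idx <- findInterval(values, seq(rng[1], rng[2], length.out = levels + 1L),
                      rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), as.integer(levels))
}
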