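# The 13 unique 3-D direction offsets (half of the 26-neighbourhood).
glcm_offsets <- function() {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  keep <- apply(offs, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  })
  offs[keep, , drop = FALSE]
}

#' Build a gray-level co-occurrence matrix from a volume of interest
#'
#' In-mask intensities are discretized into `levels` equal-width bins over
#' the ROI min-max; co-occurrences are accumulated over the 13 unique 3-D
#' direction offsets at the given voxel distance, restricted to voxel pairs
#' both inside the mask, then symmetrized and normalized to sum to 1.
#' A constant ROI follows the single-bin convention (point-mass matrix).
#'
#' @param roi a [volume_roi()].
#' @param levels number of gray levels (>= 2).
#' @param distance_voxels offset length in voxels along each direction.
#' @return An object of class `glcm`: list with `levels`, `matrix`,
#'   `distance`, `offsets`.
#' @export
glcm_build <- function(roi, levels = 32L, distance_voxels = 1L) {
  stopifnot(inherits(roi, "volume_roi"), levels >= 2L)
  lab <- array(0L, dim = dim(roi$mask))
  lab[roi$mask] <- discretize_intensities(roi$intensities[roi$mask], levels)
  glcm_from_labels(lab, roi$mask, levels, distance_voxels)
}

# Core accumulation on a pre-discretized label array (0 = outside mask).
glcm_from_labels <- function(lab, mask, levels, distance_voxels) {
  L <- as.integer(levels)
  counts <- matrix(0, L, L)
  offs <- glcm_offsets() * as.integer(distance_voxels)
  for (r in seq_len(nrow(offs))) {
    shifted_lab <- shift_array(lab, offs[r, ], fill = 0L)
    shifted_mask <- shift_array(mask, offs[r, ], fill = FALSE)
    valid <- mask & shifted_mask
    if (!any(valid)) next
    a <- lab[valid]
    b <- shifted_lab[valid]
    counts <- counts + matrix(
      tabulate((a - 1L) * L + b, nbins = L * L), L, L, byrow = TRUE
    )
  }
  counts <- counts + t(counts)
  total <- sum(counts)
  p <- if (total > 0) counts / total else counts
  structure(
    list(levels = L, matrix = p, distance = as.integer(distance_voxels),
         offsets = offs),
    class = "glcm"
  )
}

#' Informational measure of correlation (IMC1) of a GLCM
#'
#' `IMC1 = (HXY - HXY1) / max(HX, HY)` where `HXY` is the joint entropy,
#' `HX`, `HY` the marginal entropies and
#' `HXY1 = -sum p(i,j) log2(p_x(i) p_y(j))`, all in bits with the
#' `0 log 0 = 0` convention. Returns 0 when `max(HX, HY) = 0` (point-mass
#' matrix) — independence and degeneracy both map to 0.
#'
#' @param g a `glcm` object (or a normalized matrix).
#' @return A single numeric value.
#' @export
imc <- function(g) {
  p <- if (inherits(g, "glcm")) g$matrix else as.matrix(g)
  px <- rowSums(p)
  py <- colSums(p)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pp <- outer(px, py)
  keep <- p > 0 & pp > 0
  hxy1 <- -sum(p[keep] * log2(pp[keep]))
  denom <- max(hx, hy)
  if (denom == 0) return(0)
  (hxy - hxy1) / denom
}

glcm_stat_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity", "energy",
    "entropy", "homogeneity1", "homogeneity2", "imc1", "imc2", "idmn",
    "idn", "inverse_variance", "joint_average", "max_probability", "mcc",
    "sum_average", "sum_entropy", "sum_variance", "sum_squares")
}

#' All co-occurrence statistics of a GLCM
#'
#' Haralick-style statistics of a symmetric normalized GLCM, using log base
#' 2 entropies and the `0 log 0 = 0` convention.
#'
#' @param g a `glcm` object.
#' @return Named numeric vector over [glcm_stat_names()].
#' @export
glcm_features <- function(g) {
  p <- g$matrix
  L <- g$levels
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(i * p)
  muy <- sum(j * p)
  sdx <- sqrt(sum((i - mux)^2 * p))
  sdy <- sqrt(sum((j - muy)^2 * p))

  # diagonal-band distributions
  k_diff <- 0:(L - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * L)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))

  ent <- function(q) -sum(q[q > 0] * log2(q[q > 0]))
  hx <- ent(px); hy <- ent(py); hxy <- ent(p)
  pp <- outer(px, py)
  keep <- p > 0 & pp > 0
  hxy1 <- -sum(p[keep] * log2(pp[keep]))
  hxy2 <- ent(pp)

  da <- sum(k_diff * p_diff)
  sa <- sum(k_sum * p_sum)
  corr <- if (sdx > 0 && sdy > 0) (sum(i * j * p) - mux * muy) / (sdx * sdy) else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- {
    arg <- 1 - exp(-2 * log(2) * (hxy2 - hxy))
    if (arg <= 0) 0 else sqrt(arg)
  }

  c(autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    cluster_tendency = sum((i + j - mux - muy)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = ent(p_diff),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    entropy = hxy,
    homogeneity1 = sum(p / (1 + abs(i - j))),
    homogeneity2 = sum(p / (1 + (i - j)^2)),
    imc1 = imc1,
    imc2 = imc2,
    idmn = sum(p / (1 + ((i - j) / L)^2)),
    idn = sum(p / (1 + abs(i - j) / L)),
    inverse_variance = sum(p[i != j] / (i - j)[i != j]^2),
    joint_average = mux,
    max_probability = max(p),
    mcc = glcm_mcc(p, px, py),
    sum_average = sa,
    sum_entropy = ent(p_sum),
    sum_variance = sum((k_sum - sa)^2 * p_sum),
    sum_squares = sum((i - mux)^2 * p))
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k)), on the support of p_x.
glcm_mcc <- function(p, px, py) {
  sup <- px > 0
  if (sum(sup) < 2L) return(0)
  ps <- p[sup, sup, drop = FALSE]
  pxs <- px[sup]
  pys <- py[sup]
  pys[pys == 0] <- 1  # columns with zero marginal contribute nothing
  a <- ps / pxs              # a[i,k] = p(i,k)/px(i)
  b <- t(t(ps) / pys)        # b[j,k] = p(j,k)/py(k)
  q <- a %*% t(b)
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2L) return(0)
  sqrt(max(0, min(1, ev[2])))
}
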