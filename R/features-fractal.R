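# Box-counting dimension of a set of voxels: slope of log N(eps) against
# log(1/eps) over a dyadic ladder of box edge lengths (in voxels).
box_count_dimension <- function(mask, min_points = 3L) {
  coords <- mask_coords(mask)
  max_eps <- max(2L, floor(min(dim(mask)) / 4))
  sizes <- 2^(0:floor(log2(max_eps)))
  sizes <- unique(c(1L, sizes))
  counts <- vapply(sizes, function(eps) {
    boxes <- floor((coords - 1L) / eps)
    nrow(unique(boxes))
  }, numeric(1))
  usable <- counts > 0
  if (sum(usable) < min_points) return(NA_real_)
  fit <- stats::lm(log(counts[usable]) ~ log(1 / sizes[usable]))
  unname(coef(fit)[2])
}

# Differential box counting of the in-mask intensity surface: intensities
# are discretized; per eps-box the count is the number of gray-level boxes
# of height h = eps * levels / min(dim) spanned by the in-box range.
dbc_dimension <- function(roi, levels = 32L, min_points = 3L) {
  coords <- mask_coords(roi$mask)
  g <- discretize_intensities(roi$intensities[roi$mask], levels)
  max_eps <- max(2L, floor(min(dim(roi$mask)) / 4))
  sizes <- seq(2L, max(2L, max_eps))
  scale_h <- levels / min(dim(roi$mask))
  counts <- vapply(sizes, function(eps) {
    box <- floor((coords - 1L) / eps)
    key <- box[, 1] + box[, 2] * 1e3 + box[, 3] * 1e6
    h <- max(1, eps * scale_h)
    gm <- tapply(g, key, function(v) {
      floor(max(v) / h) - floor(min(v) / h) + 1
    })
    sum(gm)
  }, numeric(1))
  usable <- counts > 0
  if (sum(usable) < min_points) return(NA_real_)
  fit <- stats::lm(log(counts[usable]) ~ log(1 / sizes[usable]))
  unname(coef(fit)[2])
}

# Gliding-box lacunarity of the mask occupancy at a fixed box edge (voxels):
# E[M^2]/E[M]^2 - 1 over all box positions inside the mask bounding box.
gliding_box_lacunarity <- function(mask, box_vox = 3L) {
  coords <- mask_coords(mask)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(sub)
  if (any(d < box_vox)) return(NA_real_)
  # integral volume for O(1) box sums
  cs <- array(as.numeric(sub), dim = d)
  for (ax in 1:3) cs <- apply_cumsum_axis(cs, ax)
  n_pos <- d - box_vox + 1L
  m_vals <- numeric(prod(n_pos))
  idx <- 1L
  pad <- function(a, i, j, k) {
    if (i < 1 || j < 1 || k < 1) 0 else a[i, j, k]
  }
  for (k in seq_len(n_pos[3])) {
    for (jj in seq_len(n_pos[2])) {
      for (ii in seq_len(n_pos[1])) {
        i2 <- ii + box_vox - 1L; j2 <- jj + box_vox - 1L; k2 <- k + box_vox - 1L
        i1 <- ii - 1L; j1 <- jj - 1L; k1 <- k - 1L
        m_vals[idx] <- pad(cs, i2, j2, k2) -
          pad(cs, i1, j2, k2) - pad(cs, i2, j1, k2) - pad(cs, i2, j2, k1) +
          pad(cs, i1, j1, k2) + pad(cs, i1, j2, k1) + pad(cs, i2, j1, k1) -
          pad(cs, i1, j1, k1)
        idx <- idx + 1L
      }
    }
  }
  mu <- mean(m_vals)
  if (mu == 0) return(NA_real_)
  mean(m_vals^2) / mu^2 - 1
}

apply_cumsum_axis <- function(x, ax) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[ax])
  m <- apply(m, 2, cumsum)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Fractal features of a volume of interest
#'
#' Three descriptors of geometric and textural self-similarity: the
#' box-counting dimension of the mask boundary, the differential
#' box-counting dimension of the in-mask intensity surface, and the
#' gliding-box lacunarity of the mask occupancy at a fixed box size.
#'
#' @param roi a [volume_roi()].
#' @param lacunarity_box_vox gliding-box edge length in voxels.
#' @return Named numeric vector: `boundary_dim`, `intensity_dim`,
#'   `lacunarity`. Entries are `NA` when fewer than 3 usable ladder points
#'   exist.
#' @export
fractal_features <- function(roi, lacunarity_box_vox = 3L) {
  c(boundary_dim = box_count_dimension(boundary_mask(roi$mask)),
    intensity_dim = dbc_dimension(roi),
    lacunarity = gliding_box_lacunarity(roi$mask, lacunarity_box_vox))
}
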