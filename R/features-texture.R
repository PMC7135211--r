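# Gray-level run length, size zone, neighbourhood tone difference and
# dependence matrices, all computed on 32-level equal-width discretized
# intensities with 26-connectivity (13 unique directions).

glrlm_stat_names <- function() {
  c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv", "re",
    "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")
}

glszm_stat_names <- function() {
  c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv", "zv", "ze",
    "lglze", "hglze", "salgle", "sahgle", "lalgle", "lahgle")
}

ngtdm_stat_names <- function() {
  c("coarseness", "contrast", "busyness", "complexity", "strength")
}

gldm_stat_names <- function() {
  c("sde", "lde", "gln", "dn", "dv", "de")
}

# Discretized in-mask labels (0 outside the mask) plus voxel bookkeeping.
texture_labels <- function(roi, levels) {
  lab <- array(0L, dim = dim(roi$mask))
  lab[roi$mask] <- discretize_intensities(roi$intensities[roi$mask], levels)
  lab
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along the 13 unique 3-D
#' directions, restricted to mask voxels (a gap in the mask breaks a run).
#'
#' @param roi a [volume_roi()].
#' @param levels gray levels for discretization.
#' @return Matrix `levels x max_run_length` of run counts.
#' @export
glrlm_build <- function(roi, levels = 32L) {
  lab <- texture_labels(roi, levels)
  coords <- mask_coords(roi$mask)
  vals <- lab[roi$mask]
  d <- dim(roi$mask)
  offs <- glcm_offsets()
  runs_level <- integer(0)
  runs_len <- integer(0)
  big <- max(d) + 2L
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ax <- which(o != 0)[1]
    s <- coords[, ax] * o[ax]
    base <- coords - outer(s, o)
    line_id <- (base[, 1] + big) +
      (base[, 2] + big) * (3L * big) +
      (base[, 3] + big) * (3L * big)^2
    ord <- order(line_id, s)
    li <- line_id[ord]; si <- s[ord]; vi <- vals[ord]
    n <- length(vi)
    brk <- c(TRUE, li[-1] != li[-n] | si[-1] != si[-n] + 1L | vi[-1] != vi[-n])
    run_id <- cumsum(brk)
    runs_len <- c(runs_len, tabulate(run_id))
    runs_level <- c(runs_level, vi[brk])
  }
  max_len <- max(runs_len)
  matrix(tabulate((runs_len - 1L) * as.integer(levels) + runs_level,
                  nbins = levels * max_len),
         nrow = levels, ncol = max_len)
}

# Shared statistics for run-length-type matrices P(gray level, size).
size_matrix_stats <- function(m, n_voxels, prefix) {
  Ns <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  l <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  p <- m / Ns
  mu_i <- sum(i * p)
  mu_l <- sum(l * p)
  row_m <- rowSums(m)
  col_m <- colSums(m)
  p_sz <- col_m / Ns
  stats <- c(
    sum(m / l^2) / Ns,                     # small emphasis
    sum(m * l^2) / Ns,                     # large emphasis
    sum(row_m^2) / Ns,                     # gray level non-uniformity
    sum(row_m^2) / Ns^2,                   # .. normalized
    sum(col_m^2) / Ns,                     # size non-uniformity
    sum(col_m^2) / Ns^2,                   # .. normalized
    Ns / n_voxels,                         # run/zone percentage
    sum((i - mu_i)^2 * p),                 # gray level variance
    sum((l - mu_l)^2 * p),                 # size variance
    -sum(p[p > 0] * log2(p[p > 0])),       # entropy
    sum(m / i^2) / Ns,                     # low gray level emphasis
    sum(m * i^2) / Ns,                     # high gray level emphasis
    sum(m / (i^2 * l^2)) / Ns,             # small + low
    sum((m * i^2) / l^2) / Ns,             # small + high
    sum((m * l^2) / i^2) / Ns,             # large + low
    sum(m * i^2 * l^2) / Ns                # large + high
  )
  setNames(stats, prefix)
}

#' @rdname glrlm_build
#' @export
glrlm_features <- function(roi, levels = 32L) {
  m <- glrlm_build(roi, levels)
  size_matrix_stats(m, sum(roi$mask), glrlm_stat_names())
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level within the mask.
#'
#' @param roi a [volume_roi()].
#' @param levels gray levels for discretization.
#' @return Matrix `levels x max_zone_size` of zone counts.
#' @export
glszm_build <- function(roi, levels = 32L) {
  lab <- texture_labels(roi, levels)
  mask <- roi$mask
  vox_id <- array(0L, dim = dim(mask))
  coords <- mask_coords(mask)
  n_vox <- nrow(coords)
  vox_id[mask] <- seq_len(n_vox)
  vals <- lab[mask]
  offs <- glcm_offsets()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    shifted_id <- shift_array(vox_id, offs[r, ], fill = 0L)
    shifted_lab <- shift_array(lab, offs[r, ], fill = -1L)
    sel <- mask & shifted_id > 0L & shifted_lab == lab
    if (!any(sel)) next
    from <- c(from, vox_id[sel])
    to <- c(to, shifted_id[sel])
  }
  comp <- union_find_components(n_vox, from, to)
  zone_sizes <- tabulate(comp)
  zone_level <- vals[match(seq_len(max(comp)), comp)]
  keep <- zone_sizes > 0
  zone_sizes <- zone_sizes[keep]
  zone_level <- zone_level[keep]
  max_sz <- max(zone_sizes)
  matrix(tabulate((zone_sizes - 1L) * as.integer(levels) + zone_level,
                  nbins = levels * max_sz),
         nrow = levels, ncol = max_sz)
}

# Weighted-union union-find with path compression over 1..n and edge lists.
union_find_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' @rdname glszm_build
#' @export
glszm_features <- function(roi, levels = 32L) {
  m <- glszm_build(roi, levels)
  size_matrix_stats(m, sum(roi$mask), glszm_stat_names())
}

# 26-neighbourhood mean gray level for every mask voxel (in-mask
# neighbours only); returns list(avg, count).
neighbour_average <- function(lab, mask) {
  offs_half <- glcm_offsets()
  offs <- rbind(offs_half, -offs_half)
  sum_arr <- array(0, dim = dim(lab))
  cnt_arr <- array(0L, dim = dim(lab))
  for (r in seq_len(nrow(offs))) {
    sum_arr <- sum_arr + shift_array(lab, offs[r, ], fill = 0L)
    cnt_arr <- cnt_arr + shift_array(mask, offs[r, ], fill = FALSE)
  }
  list(sum = sum_arr, count = cnt_arr)
}

#' Neighbourhood gray-tone difference features
#'
#' @param roi a [volume_roi()].
#' @param levels gray levels for discretization.
#' @return Named numeric vector: coarseness, contrast, busyness, complexity,
#'   strength.
#' @export
ngtdm_features <- function(roi, levels = 32L) {
  lab <- texture_labels(roi, levels)
  nb <- neighbour_average(lab, roi$mask)
  valid <- roi$mask & nb$count > 0L
  g <- lab[valid]
  abar <- nb$sum[valid] / nb$count[valid]
  nvp <- sum(valid)
  lev <- sort(unique(g))
  n_i <- vapply(lev, function(l) sum(g == l), numeric(1))
  s_i <- vapply(lev, function(l) sum(abs(l - abar[g == l])), numeric(1))
  p_i <- n_i / nvp
  ngp <- length(lev)
  eps <- .Machine$double.eps

  coarseness <- 1 / max(sum(p_i * s_i), eps)
  contrast <- if (ngp > 1) {
    (sum(outer(p_i, p_i) * outer(lev, lev, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0
  busyness <- {
    den <- sum(abs(outer(lev * p_i, lev * p_i, `-`)))
    if (den > 0) sum(p_i * s_i) / den else 0
  }
  complexity <- if (ngp > 1) {
    num <- 0
    for (a in seq_along(lev)) {
      for (b in seq_along(lev)) {
        den_ab <- p_i[a] + p_i[b]
        if (den_ab > 0) {
          num <- num + abs(lev[a] - lev[b]) *
            (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / den_ab
        }
      }
    }
    num / nvp
  } else 0
  strength <- {
    num <- sum(outer(p_i, p_i, `+`) * outer(lev, lev, `-`)^2)
    if (sum(s_i) > 0) num / sum(s_i) else 0
  }
  setNames(c(coarseness, contrast, busyness, complexity, strength),
           ngtdm_stat_names())
}

#' Gray-level dependence features
#'
#' Dependence of a voxel = 1 + number of 26-neighbours (within the mask)
#' whose discretized gray level equals the voxel's own (tolerance `alpha`).
#'
#' @param roi a [volume_roi()].
#' @param levels gray levels for discretization.
#' @param alpha dependence tolerance in gray levels.
#' @return Named numeric vector over [gldm_stat_names()].
#' @export
gldm_features <- function(roi, levels = 32L, alpha = 0L) {
  m <- gldm_build(roi, levels, alpha)
  Nd <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  jm <- t(matrix(seq_len(ncol(m)), ncol(m), nrow(m)))
  p <- m / Nd
  mu_j <- sum(jm * p)
  row_m <- rowSums(m)
  col_m <- colSums(m)
  setNames(c(
    sum(m / jm^2) / Nd,
    sum(m * jm^2) / Nd,
    sum(row_m^2) / Nd,
    sum(col_m^2) / Nd,
    sum((jm - mu_j)^2 * p),
    -sum(p[p > 0] * log2(p[p > 0]))
  ), gldm_stat_names())
}

#' @rdname gldm_features
#' @export
gldm_build <- function(roi, levels = 32L, alpha = 0L) {
  lab <- texture_labels(roi, levels)
  mask <- roi$mask
  offs_half <- glcm_offsets()
  offs <- rbind(offs_half, -offs_half)
  dep <- array(0L, dim = dim(lab))
  for (r in seq_len(nrow(offs))) {
    shifted_lab <- shift_array(lab, offs[r, ], fill = -99L)
    shifted_mask <- shift_array(mask, offs[r, ], fill = FALSE)
    dep <- dep + (mask & shifted_mask & abs(shifted_lab - lab) <= alpha)
  }
  g <- lab[mask]
  dvals <- dep[mask] + 1L
  max_d <- max(dvals)
  matrix(tabulate((dvals - 1L) * as.integer(levels) + g,
                  nbins = levels * max_d),
         nrow = levels, ncol = max_d)
}
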