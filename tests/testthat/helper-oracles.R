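# Fixture builders and independent brute-force oracles used across the
# suite. The oracles are deliberately written as naive per-voxel / per-gene
# loops, sharing no accumulation code with the package implementations.

# --- fixtures ---------------------------------------------------------------

toy_roi <- function(arr, mask = NULL, spacing = 1) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(arr))
  volume_roi(arr, mask, spacing)
}

# Random small volume with integer-ish intensities and (optionally) a
# random mask; deterministic given the seed.
random_roi <- function(dims = c(6L, 6L, 6L), seed = 1L, n_levels = 4L,
                       mask_frac = 1, spacing = 1) {
  set.seed(seed)
  arr <- array(runif(prod(dims)), dim = dims)
  mask <- array(TRUE, dim = dims)
  if (mask_frac < 1) {
    mask <- array(runif(prod(dims)) < mask_frac, dim = dims)
    if (sum(mask) < 8L) mask[1:2, 1:2, 1:2] <- TRUE
  }
  structure(volume_roi(arr, mask, spacing), n_levels = n_levels)
}

# Solid axis-aligned cuboid mask inside a padded grid.
cuboid_mask <- function(dims, lo, hi) {
  m <- array(FALSE, dim = dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

# All 26 neighbour offsets.
all_offsets_26 <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

in_bounds <- function(v, d) all(v >= 1L) && all(v <= d)

# In-mask discretized labels (0 outside), same binning as the package.
oracle_labels <- function(roi, levels) {
  lab <- array(0L, dim = dim(roi$mask))
  vals <- roi$intensities[roi$mask]
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    lab[roi$mask] <- 1L
    return(lab)
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE)
  lab[roi$mask] <- pmin(pmax(idx, 1L), levels)
  lab
}

# --- texture-matrix oracles -------------------------------------------------

# GLCM: count every ordered in-mask voxel pair over all 26 directions at
# the given distance, then normalize (26 ordered directions == the 13
# unique directions symmetrized).
oracle_glcm <- function(roi, levels, distance = 1L) {
  lab <- oracle_labels(roi, levels)
  d <- dim(lab)
  counts <- matrix(0, levels, levels)
  offs <- all_offsets_26() * distance
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!roi$mask[i, j, k]) next
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (!in_bounds(v, d)) next
      if (!roi$mask[v[1], v[2], v[3]]) next
      a <- lab[i, j, k]
      b <- lab[v[1], v[2], v[3]]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

# GLRLM: naive run walking along the 13 unique directions; a voxel starts a
# run iff its backward neighbour is outside the mask or has another label.
oracle_glrlm <- function(roi, levels) {
  lab <- oracle_labels(roi, levels)
  d <- dim(lab)
  offs <- all_offsets_26()
  offs <- offs[apply(offs, 1, function(o) o[which(o != 0)[1]] > 0), ,
               drop = FALSE]
  runs <- list()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!roi$mask[i, j, k]) next
      p <- c(i, j, k) - o
      if (in_bounds(p, d) && roi$mask[p[1], p[2], p[3]] &&
          lab[p[1], p[2], p[3]] == lab[i, j, k]) next
      len <- 1L
      v <- c(i, j, k) + o
      while (in_bounds(v, d) && roi$mask[v[1], v[2], v[3]] &&
             lab[v[1], v[2], v[3]] == lab[i, j, k]) {
        len <- len + 1L
        v <- v + o
      }
      runs[[length(runs) + 1L]] <- c(lab[i, j, k], len)
    }
  }
  runs <- do.call(rbind, runs)
  m <- matrix(0, levels, max(runs[, 2]))
  for (t in seq_len(nrow(runs))) {
    m[runs[t, 1], runs[t, 2]] <- m[runs[t, 1], runs[t, 2]] + 1
  }
  m
}

# GLSZM: flood-fill 26-connected equal-label zones.
oracle_glszm <- function(roi, levels) {
  lab <- oracle_labels(roi, levels)
  d <- dim(lab)
  seen <- array(FALSE, dim = d)
  offs <- all_offsets_26()
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!roi$mask[i, j, k] || seen[i, j, k]) next
    lvl <- lab[i, j, k]
    frontier <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(frontier) > 0) {
      cur <- frontier[[length(frontier)]]
      frontier[[length(frontier)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        v <- cur + offs[r, ]
        if (!in_bounds(v, d)) next
        if (seen[v[1], v[2], v[3]] || !roi$mask[v[1], v[2], v[3]]) next
        if (lab[v[1], v[2], v[3]] != lvl) next
        seen[v[1], v[2], v[3]] <- TRUE
        frontier[[length(frontier) + 1L]] <- v
      }
    }
    zones[[length(zones) + 1L]] <- c(lvl, size)
  }
  zones <- do.call(rbind, zones)
  m <- matrix(0, levels, max(zones[, 2]))
  for (t in seq_len(nrow(zones))) {
    m[zones[t, 1], zones[t, 2]] <- m[zones[t, 1], zones[t, 2]] + 1
  }
  m
}

# NGTDM ingredients: per present gray level, the occurrence count n_i and
# the summed absolute difference s_i to the 26-neighbourhood mean.
oracle_ngtdm <- function(roi, levels) {
  lab <- oracle_labels(roi, levels)
  d <- dim(lab)
  offs <- all_offsets_26()
  g <- integer(0)
  diffs <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!roi$mask[i, j, k]) next
    nb <- numeric(0)
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (in_bounds(v, d) && roi$mask[v[1], v[2], v[3]]) {
        nb <- c(nb, lab[v[1], v[2], v[3]])
      }
    }
    if (length(nb) == 0) next
    g <- c(g, lab[i, j, k])
    diffs <- c(diffs, abs(lab[i, j, k] - mean(nb)))
  }
  lev <- sort(unique(g))
  list(
    levels = lev,
    n_i = vapply(lev, function(l) sum(g == l), numeric(1)),
    s_i = vapply(lev, function(l) sum(diffs[g == l]), numeric(1)),
    n_valid = length(g)
  )
}

# GLDM: dependence = 1 + number of in-mask 26-neighbours with equal label.
oracle_gldm <- function(roi, levels) {
  lab <- oracle_labels(roi, levels)
  d <- dim(lab)
  offs <- all_offsets_26()
  pairs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!roi$mask[i, j, k]) next
    dep <- 1L
    for (r in seq_len(nrow(offs))) {
      v <- c(i, j, k) + offs[r, ]
      if (in_bounds(v, d) && roi$mask[v[1], v[2], v[3]] &&
          lab[v[1], v[2], v[3]] == lab[i, j, k]) {
        dep <- dep + 1L
      }
    }
    pairs[[length(pairs) + 1L]] <- c(lab[i, j, k], dep)
  }
  pairs <- do.call(rbind, pairs)
  m <- matrix(0, levels, max(pairs[, 2]))
  for (t in seq_len(nrow(pairs))) {
    m[pairs[t, 1], pairs[t, 2]] <- m[pairs[t, 1], pairs[t, 2]] + 1
  }
  m
}

# Pad a matrix with zero columns so two count matrices can be compared even
# when their trailing all-zero columns differ.
pad_cols <- function(m, ncols) {
  if (ncol(m) >= ncols) return(m)
  cbind(m, matrix(0, nrow(m), ncols - ncol(m)))
}

expect_matrix_equal <- function(got, want, tol = 1e-10) {
  nc <- max(ncol(got), ncol(want))
  expect_lt(max(abs(pad_cols(got, nc) - pad_cols(want, nc))), tol)
}

# --- ssGSEA oracle ----------------------------------------------------------

# Independent ranked-walk: walk genes in decreasing expression order,
# keeping explicit running numerators instead of cumsum vectors.
oracle_ssgsea <- function(expr_vec, gene_set, alpha = 0.25) {
  n <- length(expr_vec)
  ord <- order(-expr_vec, seq_len(n))
  genes <- names(expr_vec)[ord]
  member <- genes %in% gene_set
  m <- sum(member)
  denom_in <- sum(((n:1)[member])^alpha)
  score <- 0
  acc_in <- 0
  acc_out <- 0
  for (pos in seq_len(n)) {
    rank_val <- n - pos + 1
    if (member[pos]) {
      acc_in <- acc_in + rank_val^alpha / denom_in
    } else {
      acc_out <- acc_out + 1 / (n - m)
    }
    score <- score + (acc_in - acc_out)
  }
  score
}
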