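# Trilinear interpolation of a 3-D array at physical coordinates (mm).
# Points outside the grid return the nearest edge value.
interp_trilinear <- function(arr, spacing_mm, pts_mm) {
  d <- dim(arr)
  # voxel-centre coordinates: voxel i sits at i * spacing
  fi <- pmin(pmax(pts_mm[, 1] / spacing_mm[1], 1), d[1])
  fj <- pmin(pmax(pts_mm[, 2] / spacing_mm[2], 1), d[2])
  fk <- pmin(pmax(pts_mm[, 3] / spacing_mm[3], 1), d[3])
  i0 <- pmin(floor(fi), d[1] - 1L); j0 <- pmin(floor(fj), d[2] - 1L)
  k0 <- pmin(floor(fk), d[3] - 1L)
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- (1 - wi) * (1 - wj) * (1 - wk) * at(i0, j0, k0) +
    wi * (1 - wj) * (1 - wk) * at(i0 + 1, j0, k0) +
    (1 - wi) * wj * (1 - wk) * at(i0, j0 + 1, k0) +
    (1 - wi) * (1 - wj) * wk * at(i0, j0, k0 + 1) +
    wi * wj * (1 - wk) * at(i0 + 1, j0 + 1, k0) +
    wi * (1 - wj) * wk * at(i0 + 1, j0, k0 + 1) +
    (1 - wi) * wj * wk * at(i0, j0 + 1, k0 + 1) +
    wi * wj * wk * at(i0 + 1, j0 + 1, k0 + 1)
  v
}

# Outward surface normals at given boundary voxels, estimated from the
# gradient of a Gaussian-smoothed mask occupancy field.
surface_normals <- function(mask, spacing_mm, coords) {
  occ <- gaussian_smooth3d(array(as.numeric(mask), dim = dim(mask)),
                           2 * min(spacing_mm), spacing_mm)
  grads <- vapply(1:3, function(ax) {
    # convolve_axis correlates (no kernel flip): this ordering gives the
    # forward central difference (x[i+1] - x[i-1]) / (2h)
    kern <- c(-1, 0, 1) / (2 * spacing_mm[ax])
    g <- convolve_axis(occ, kern, ax)
    g[coords]
  }, numeric(nrow(coords)))
  grads <- matrix(grads, ncol = 3)
  # occupancy decreases outward, so the outward normal is -gradient
  nrm <- -grads
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-9] <- NA_real_
  nrm / len
}

#' Tumor-margin sigmoid features
#'
#' Samples intensity profiles along outward surface normals through seeded
#' boundary points and fits a logistic step
#' `f(d) = b + A / (1 + exp(-(d - c) / s))` to each by Levenberg-Marquardt
#' least squares. Features are the mean and SD over converged profiles of
#' the amplitude `|A|` (intensity step across the margin), the slope
#' parameter `|s|` (logistic scale, mm) and the center `c` (mm, relative to
#' the nominal surface). Non-converged fits are dropped; if fewer than 20%
#' of profiles converge all six features are missing.
#'
#' @param roi a [volume_roi()].
#' @param n_profiles number of boundary points to sample.
#' @param profile_len_mm half-length of each profile (mm).
#' @param seed RNG seed for boundary point sampling.
#' @return Named numeric vector: `amplitude_mean`, `amplitude_sd`,
#'   `slope_mean`, `slope_sd`, `center_mean`, `center_sd`, with attribute
#'   `n_converged`.
#' @export
sigmoid_features <- function(roi, n_profiles = 30L, profile_len_mm = 8,
                             seed = 1L) {
  bnd <- boundary_mask(roi$mask)
  coords <- mask_coords(bnd)
  if (nrow(coords) == 0L) stop("mask has no boundary voxels", call. = FALSE)
  idx <- with_seed(derive_seed(seed, "sigmoid-profiles"), {
    sample(nrow(coords), min(n_profiles, nrow(coords)))
  })
  coords <- coords[idx, , drop = FALSE]
  normals <- surface_normals(roi$mask, roi$spacing_mm, coords)
  valid <- stats::complete.cases(normals)
  coords <- coords[valid, , drop = FALSE]
  normals <- normals[valid, , drop = FALSE]
  n_use <- nrow(normals)
  if (n_use == 0L) stop("no usable surface normals", call. = FALSE)
  step <- min(roi$spacing_mm) / 2
  d_grid <- seq(-profile_len_mm, profile_len_mm, by = step)

  fits <- purrr::map(seq_len(n_use), function(pi) {
    origin <- coords[pi, ] * roi$spacing_mm
    pts <- cbind(origin[1] + d_grid * normals[pi, 1],
                 origin[2] + d_grid * normals[pi, 2],
                 origin[3] + d_grid * normals[pi, 3])
    y <- interp_trilinear(roi$intensities, roi$spacing_mm, pts)
    fit_logistic_profile(d_grid, y)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(ok) < 0.2 * n_use) {
    warning(sprintf("only %d/%d margin profiles converged; sigmoid features set to missing",
                    sum(ok), n_use), call. = FALSE)
    out <- setNames(rep(NA_real_, 6),
                    c("amplitude_mean", "amplitude_sd", "slope_mean",
                      "slope_sd", "center_mean", "center_sd"))
    attr(out, "n_converged") <- sum(ok)
    return(out)
  }
  pars <- dplyr::bind_rows(fits[ok])
  out <- c(amplitude_mean = mean(pars$amplitude),
           amplitude_sd = sd(pars$amplitude),
           slope_mean = mean(pars$slope),
           slope_sd = sd(pars$slope),
           center_mean = mean(pars$center),
           center_sd = sd(pars$center))
  # a single converged profile has no spread
  out[is.na(out)] <- 0
  attr(out, "n_converged") <- sum(ok)
  out
}

# Least-squares logistic fit of one margin profile; NULL if the fit fails.
fit_logistic_profile <- function(d, y) {
  n <- length(y)
  lo <- mean(head(y, 3)); hi <- mean(tail(y, 3))
  start <- list(b = lo, A = hi - lo, c = 0, s = diff(range(d)) / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + A / (1 + exp(-(d - c) / s)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (!all(is.finite(cf))) return(NULL)
  # reject extrapolated fits: a step centered outside the sampled profile,
  # or an amplitude beyond the profile's dynamic range, is not a margin
  # measurement but an artifact of fitting an unconstrained logistic
  if (cf[["c"]] < min(d) || cf[["c"]] > max(d)) return(NULL)
  if (abs(cf[["A"]]) > 3 * diff(range(y)) + .Machine$double.eps) return(NULL)
  tibble::tibble(amplitude = abs(cf[["A"]]), slope = abs(cf[["s"]]),
                 center = cf[["c"]])
}
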