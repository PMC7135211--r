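#' Shape features of a tumor mask
#'
#' Voxel-based 3-D morphology: volume, surface area (exposed voxel faces,
#' spacing-aware), surface-to-volume ratio, sphericity, two compactness
#' variants, spherical disproportion, maximum 3-D diameter, and the
#' elongation and flatness principal-axis ratios.
#'
#' @param mask 3-D logical array.
#' @param spacing_mm per-axis voxel size (mm).
#' @return Named numeric vector of 10 features.
#' @export
shape_features <- function(mask, spacing_mm) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  n_vox <- sum(mask)
  if (n_vox == 0L) stop("empty mask", call. = FALSE)
  vox_vol <- prod(spacing_mm)
  volume <- n_vox * vox_vol

  # exposed faces per axis: mask voxel whose +/- neighbour is outside
  face_area <- c(spacing_mm[2] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[2])
  area <- 0
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      offset <- c(0L, 0L, 0L); offset[ax] <- s
      exposed <- mask & !shift_array(mask, offset, fill = FALSE)
      area <- area + sum(exposed) * face_area[ax]
    }
  }

  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area
  compactness1 <- volume / (sqrt(pi) * area^1.5)
  compactness2 <- 36 * pi * volume^2 / area^3
  r_eq <- (3 * volume / (4 * pi))^(1 / 3)
  spherical_disproportion <- area / (4 * pi * r_eq^2)

  bnd <- boundary_mask(mask)
  bc <- mask_coords(if (any(bnd)) bnd else mask)
  bc_mm <- sweep(bc, 2, spacing_mm, `*`)
  max_diam <- max_pairwise_distance(bc_mm)

  coords_mm <- sweep(mask_coords(mask), 2, spacing_mm, `*`)
  if (nrow(coords_mm) > 1L) {
    ev <- sort(eigen(stats::cov(coords_mm), only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  } else {
    elongation <- 0; flatness <- 0
  }

  c(volume = volume,
    surface_area = area,
    surface_to_volume = area / volume,
    sphericity = sphericity,
    compactness1 = compactness1,
    compactness2 = compactness2,
    spherical_disproportion = spherical_disproportion,
    max_diameter_3d = max_diam,
    elongation = elongation,
    flatness = flatness)
}

# Largest pairwise Euclidean distance, chunked to bound memory.
max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  best <- 0
  chunk <- 500L
  sq <- rowSums(pts^2)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * pts[rows, , drop = FALSE] %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Physical features of a volume of interest
#'
#' Tumor volume (mm^3), a mass surrogate (volume times mean density with HU
#' rescaled so water = 1: `volume * mean(HU + 1000) / 1000`), and the
#' largest axial (third-axis) cross-sectional area (mm^2).
#'
#' @param roi a [volume_roi()].
#' @return Named numeric vector: `volume_mm3`, `mass`, `max_axial_area_mm2`.
#' @export
physical_features <- function(roi) {
  vox_vol <- prod(roi$spacing_mm)
  volume <- sum(roi$mask) * vox_vol
  mass <- volume * mean(roi$intensities[roi$mask] + 1000) / 1000
  slice_counts <- apply(roi$mask, 3, sum)
  max_area <- max(slice_counts) * roi$spacing_mm[1] * roi$spacing_mm[2]
  c(volume_mm3 = volume, mass = mass, max_axial_area_mm2 = max_area)
}
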