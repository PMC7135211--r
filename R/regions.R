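#' Decompose a tumor mask into inner core and outer rim regions
#'
#' Splits the tumor into an `inner` region (the mask eroded by
#' `rim_depth_mm`, metric-aware in millimetres) and an `outer` peritumoral
#' shell (mask minus inner). "Delta" values are built by a seeded random
#' pairing of equal-sized subsamples of outer and inner voxel intensities,
#' elementwise `outer - inner`, so statistics of the rim-core intensity
#' difference can be computed; `deltaS` is a further seeded subsample of the
#' delta values.
#'
#' @param roi a [volume_roi()].
#' @param rim_depth_mm erosion depth defining the rim thickness (mm).
#' @param subsample_frac fraction of delta values retained in `deltaS`.
#' @param seed RNG seed for the pairing and subsampling.
#' @return An object of class `region_set`: list with `inner_mask`,
#'   `outer_mask`, `delta_values`, `deltaS_values`, `rng_seed`.
#' @export
decompose_regions <- function(roi, rim_depth_mm = 2, subsample_frac = 0.5,
                              seed = 1L) {
  stopifnot(inherits(roi, "volume_roi"))
  inner <- erode_mask_mm(roi$mask, roi$spacing_mm, rim_depth_mm)
  if (!any(inner)) {
    stop(sprintf(
      "erosion by rim_depth_mm = %.2f empties the inner region; use a smaller rim_depth_mm",
      rim_depth_mm
    ), call. = FALSE)
  }
  outer <- roi$mask & !inner
  if (!any(outer)) {
    stop("outer region is empty: rim_depth_mm too small for the voxel spacing",
         call. = FALSE)
  }
  out_vals <- roi$intensities[outer]
  in_vals <- roi$intensities[inner]
  n_pairs <- min(length(out_vals), length(in_vals))
  delta <- with_seed(derive_seed(seed, "delta-pairing"), {
    o <- sample(out_vals, n_pairs)
    i <- sample(in_vals, n_pairs)
    o - i
  })
  n_sub <- max(2L, floor(subsample_frac * length(delta)))
  n_sub <- min(n_sub, length(delta))
  deltaS <- with_seed(derive_seed(seed, "delta-subsample"), {
    sample(delta, n_sub)
  })
  structure(
    list(inner_mask = inner, outer_mask = outer,
         delta_values = delta, deltaS_values = deltaS,
         rng_seed = as.integer(seed)),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf(
    "<region_set> inner %d voxels, outer %d voxels, %d delta pairs (%d subsampled), seed %d\n",
    sum(x$inner_mask), sum(x$outer_mask),
    length(x$delta_values), length(x$deltaS_values), x$rng_seed
  ))
  invisible(x)
}
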