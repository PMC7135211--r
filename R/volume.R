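#' Volume of interest: a 3-D intensity grid with a tumor mask
#'
#' Bundles a 3-D scalar intensity array (Hounsfield units), a binary tumor
#' mask of the same shape, and the per-axis voxel spacing in millimetres.
#' This is the unit of radiomic analysis: every feature extractor takes one.
#'
#' @param intensities 3-D numeric array of voxel intensities (HU).
#' @param mask 3-D logical or 0/1 array, same dimensions; `TRUE` marks tumor
#'   voxels. Must be non-empty.
#' @param spacing_mm numeric length-3, voxel size along each axis in mm.
#' @return An object of class `volume_roi`.
#' @export
volume_roi <- function(intensities, mask, spacing_mm) {
  if (length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3-D array", call. = FALSE)
  }
  if (!identical(dim(intensities), dim(mask))) {
    stop("`mask` dimensions must match `intensities`", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  if (!any(mask)) stop("`mask` is empty: no tumor voxels", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  }
  structure(
    list(intensities = intensities, mask = mask, spacing_mm = spacing_mm),
    class = "volume_roi"
  )
}

#' @export
print.volume_roi <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<volume_roi> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm, %d tumor voxels\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    sum(x$mask)
  ))
  rng <- range(x$intensities[x$mask])
  cat(sprintf("  in-mask intensity range: [%.1f, %.1f] HU\n", rng[1], rng[2]))
  invisible(x)
}

# Integer voxel coordinates (n x 3) of TRUE entries of a 3-D logical array.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# Metric-aware binary erosion: a voxel stays TRUE iff the ball of radius
# `radius_mm` around its centre (in physical units) lies entirely inside the
# mask. Implemented by erasing every mask voxel within radius_mm of a
# non-mask voxel (including the implicit background outside the grid).
erode_mask_mm <- function(mask, spacing_mm, radius_mm) {
  d <- dim(mask)
  # structuring element: all integer offsets with ||offset * spacing|| <= radius
  r_vox <- ceiling(radius_mm / spacing_mm)
  off <- as.matrix(expand.grid(
    i = -r_vox[1]:r_vox[1], j = -r_vox[2]:r_vox[2], k = -r_vox[3]:r_vox[3]
  ))
  dist <- sqrt((off[, 1] * spacing_mm[1])^2 +
               (off[, 2] * spacing_mm[2])^2 +
               (off[, 3] * spacing_mm[3])^2)
  off <- off[dist <= radius_mm + 1e-9, , drop = FALSE]
  out <- array(TRUE, dim = d)
  for (r in seq_len(nrow(off))) {
    out <- out & shift_array(mask, off[r, ], fill = FALSE)
  }
  out & mask
}

# Shift a 3-D array by an integer offset, filling exposed entries.
# shift_array(x, c(1,0,0))[i,j,k] == x[i+1,j,k] (out-of-range -> fill).
shift_array <- function(x, offset, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, dim = d)
  src_from <- pmax(1L, 1L + offset)
  src_to <- pmin(d, d + offset)
  if (any(src_from > src_to)) return(out)
  dst_from <- pmax(1L, 1L - offset)
  dst_to <- dst_from + (src_to - src_from)
  out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2], dst_from[3]:dst_to[3]] <-
    x[src_from[1]:src_to[1], src_from[2]:src_to[2], src_from[3]:src_to[3]]
  out
}

# Surface voxels of a mask: mask voxels with at least one 6-neighbour
# outside the mask (grid edges count as outside).
boundary_mask <- function(mask) {
  inner <- array(TRUE, dim = dim(mask))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      offset <- c(0L, 0L, 0L); offset[ax] <- s
      inner <- inner & shift_array(mask, offset, fill = FALSE)
    }
  }
  mask & !inner
}

#' Read a volume and mask from NIfTI files
#'
#' @param image_path,mask_path paths to NIfTI volumes (image and binary mask).
#' @return A [volume_roi()].
#' @export
read_volume_roi <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  volume_roi(array(as.numeric(img), dim = dim(img)[1:3]),
             array(as.numeric(msk) > 0.5, dim = dim(msk)[1:3]),
             spacing)
}

#' Write a volume and mask as NIfTI files
#'
#' @param roi a [volume_roi()].
#' @param image_path,mask_path output file paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_volume_roi <- function(roi, image_path, mask_path) {
  img <- RNifti::asNifti(roi$intensities)
  RNifti::pixdim(img) <- roi$spacing_mm
  msk <- RNifti::asNifti(array(as.integer(roi$mask), dim = dim(roi$mask)))
  RNifti::pixdim(msk) <- roi$spacing_mm
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}
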