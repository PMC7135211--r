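#' Configuration for the synthetic tumor phantom generator
#'
#' Defines the generative conditions for a cohort of quasi-ellipsoidal lung
#' tumor phantoms on a CT-like intensity scale: a soft-tissue core carrying a
#' spatially correlated texture field, a peritumoral rim whose mean intensity
#' and margin sharpness are (optionally) coupled to a latent Th2-like immune
#' state, and a sigmoid intensity transition into aerated-lung background.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3 (or scalar), voxel spacing in mm.
#' @param tumor_radius_mm mean equivalent tumor radius (mm).
#' @param core_mean_hu,rim_mean_hu mean intensity of tumor core and rim (HU).
#' @param background_hu intensity of the surrounding lung parenchyma (HU).
#' @param noise_sd_hu standard deviation of the intra-tumor texture field (HU).
#' @param texture_corr_len_mm spatial correlation length of the texture field
#'   (mm); white noise is Gaussian-smoothed to this scale.
#' @param margin_width_mm 10-90% transition distance of the logistic
#'   intensity ramp at the tumor boundary (mm); the logistic scale parameter
#'   is `margin_width_mm / (2 * log(9))`.
#' @param histogram_skew_param asymmetry of the intra-tumor intensity
#'   histogram; 0 gives a symmetric field, positive values right-skew it via
#'   an exponential warp of the texture field.
#' @param coupling_beta effect size linking the latent Th2 state to the image
#'   phenotype, in HU of rim mean shift per unit latent; margin width also
#'   scales by `exp(-0.02 * coupling_beta * th2)`, so higher Th2 brightens
#'   the rim and sharpens the margin together. 0 decouples image from
#'   immune state.
#' @param eccentricity maximal per-axis fractional deviation of the ellipsoid
#'   radii from `tumor_radius_mm` (drawn per sample).
#' @param n_samples cohort size.
#' @param seed master RNG seed; together with a sample's identity it fully
#'   determines that sample's volume.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(grid_shape = c(40L, 40L, 40L),
                           spacing_mm = c(1.5, 1.5, 1.5),
                           tumor_radius_mm = 12,
                           core_mean_hu = 30,
                           rim_mean_hu = 60,
                           background_hu = -800,
                           noise_sd_hu = 12,
                           texture_corr_len_mm = 3,
                           margin_width_mm = 2,
                           histogram_skew_param = 0.3,
                           coupling_beta = 0,
                           eccentricity = 0.1,
                           n_samples = 60L,
                           seed = 1L) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  cfg <- list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    tumor_radius_mm = tumor_radius_mm, core_mean_hu = core_mean_hu,
    rim_mean_hu = rim_mean_hu, background_hu = background_hu,
    noise_sd_hu = noise_sd_hu, texture_corr_len_mm = texture_corr_len_mm,
    margin_width_mm = margin_width_mm,
    histogram_skew_param = histogram_skew_param,
    coupling_beta = coupling_beta, eccentricity = eccentricity,
    n_samples = as.integer(n_samples), seed = as.integer(seed)
  )
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 8L))
  if (any(cfg$spacing_mm <= 0)) stop("`spacing_mm` must be positive", call. = FALSE)
  if (cfg$tumor_radius_mm <= 0) stop("`tumor_radius_mm` must be positive", call. = FALSE)
  if (cfg$margin_width_mm <= 0) stop("`margin_width_mm` must be positive", call. = FALSE)
  if (cfg$noise_sd_hu < 0) stop("`noise_sd_hu` must be non-negative", call. = FALSE)
  if (cfg$texture_corr_len_mm < 0) stop("`texture_corr_len_mm` must be non-negative", call. = FALSE)
  if (cfg$n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  # the tumor plus two margin widths must fit in the grid on every axis
  max_r <- cfg$tumor_radius_mm * (1 + cfg$eccentricity)
  for (ax in 1:3) {
    half_extent <- cfg$grid_shape[ax] * cfg$spacing_mm[ax] / 2
    if (max_r + 2 * cfg$margin_width_mm > half_extent) {
      stop(sprintf(
        "tumor (radius %.1f mm + 2 x margin %.1f mm) does not fit axis %d (half-extent %.1f mm); enlarge `grid_shape[%d]` or shrink the tumor",
        max_r, cfg$margin_width_mm, ax, half_extent, ax
      ), call. = FALSE)
    }
  }
  structure(cfg, class = "phantom_config")
}

#' Draw latent immune states for a synthetic cohort
#'
#' Latent Th1, Th2 and cytotoxic-T activities are i.i.d. standard normal,
#' mirroring the continuous signature scores that are later dichotomized at
#' the cohort mean.
#'
#' @param n number of samples.
#' @param seed RNG seed.
#' @return A tibble with columns `sample_id`, `th1_level`, `th2_level`,
#'   `ctl_level`.
#' @export
sample_latent_states <- function(n, seed = 1L) {
  with_seed(derive_seed(seed, "latent"), {
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      th1_level = rnorm(n),
      th2_level = rnorm(n),
      ctl_level = rnorm(n)
    )
  })
}

# Separable Gaussian smoothing of a 3-D array, sigma in physical units.
gaussian_smooth3d <- function(x, sigma_mm, spacing_mm) {
  for (ax in 1:3) {
    s_vox <- sigma_mm / spacing_mm[ax]
    if (s_vox < 1e-8) next
    half <- max(1L, ceiling(3 * s_vox))
    kern <- exp(-0.5 * ((-half:half) / s_vox)^2)
    kern <- kern / sum(kern)
    x <- convolve_axis(x, kern, ax)
  }
  x
}

# Convolve a 3-D array along one axis with a centered 1-D kernel,
# replicating edge values (so a constant array stays constant).
convolve_axis <- function(x, kern, ax) {
  d <- dim(x)
  half <- (length(kern) - 1L) %/% 2L
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  # pad by edge replication
  pad_top <- m[rep(1L, half), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), half), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (t in seq_along(kern)) {
    out <- out + kern[t] * mp[t:(t + dp[1] - 1L), , drop = FALSE]
  }
  aperm(array(out, dim = dp), order(perm))
}

# Per-sample deterministic seed for phantom synthesis.
phantom_seed <- function(config, sample_id) {
  derive_seed(config$seed, paste0("phantom:", sample_id))
}

#' Generate one synthetic tumor phantom
#'
#' Builds a quasi-ellipsoidal tumor in a CT-like volume. The intensity model
#' is `background + (plateau + texture - background) * ramp`, where the
#' plateau rises from the core mean to the rim mean over the outer 2 mm of
#' the tumor, `ramp` is a logistic function of the signed distance to the
#' tumor surface with width `margin_width_mm` (scaled by the latent Th2
#' state when `coupling_beta != 0`), and the texture field is Gaussian-
#' correlated noise, optionally warped to a skewed marginal distribution.
#' The rim mean is shifted by `coupling_beta * th2_level` HU.
#'
#' @param config a [phantom_config()].
#' @param state one row of [sample_latent_states()] (or a list with
#'   `sample_id`, `th1_level`, `th2_level`, `ctl_level`).
#' @return A [volume_roi()] with attribute `sample_id`.
#' @export
generate_phantom <- function(config, state) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  sp <- config$spacing_mm
  th2 <- as.numeric(state$th2_level)

  with_seed(phantom_seed(config, state$sample_id), {
    # per-sample ellipsoid radii
    radii <- config$tumor_radius_mm *
      (1 + config$eccentricity * runif(3, -1, 1))

    # physical coordinates relative to the grid centre
    ctr <- (d + 1) / 2 * sp
    ax_mm <- lapply(1:3, function(a) (seq_len(d[a]) * sp[a]) - ctr[a])
    X <- array(rep(ax_mm[[1]], times = d[2] * d[3]), dim = d)
    Y <- array(rep(rep(ax_mm[[2]], each = d[1]), times = d[3]), dim = d)
    Z <- array(rep(ax_mm[[3]], each = d[1] * d[2]), dim = d)

    rho2 <- (X / radii[1])^2 + (Y / radii[2])^2 + (Z / radii[3])^2
    rho <- sqrt(rho2)
    # first-order signed distance to the implicit surface rho = 1 (mm)
    grad <- sqrt((X / radii[1]^2)^2 + (Y / radii[2]^2)^2 + (Z / radii[3]^2)^2)
    grad[grad < 1e-12] <- 1e-12
    d_out <- (rho - 1) * rho / grad  # negative inside the tumor

    mask <- d_out <= 0

    # plateau: core -> (possibly Th2-shifted) rim over the outer rim shell
    rim_mean <- config$rim_mean_hu + config$coupling_beta * th2
    rim_w <- exp(pmin(d_out, 0) / 2)  # 1 at the surface, decays 2 mm inward
    plateau <- config$core_mean_hu +
      (rim_mean - config$core_mean_hu) * rim_w

    # correlated, optionally skew-warped texture field
    if (config$noise_sd_hu > 0) {
      z <- array(rnorm(prod(d)), dim = d)
      z <- gaussian_smooth3d(z, config$texture_corr_len_mm, sp)
      z <- z / max(sd(z), 1e-12)
      g <- config$histogram_skew_param
      if (abs(g) > 1e-12) {
        z <- (exp(g * z) - 1) / g
        z <- (z - mean(z)) / max(sd(z), 1e-12)
      }
      texture <- config$noise_sd_hu * z
    } else {
      texture <- 0
    }

    # margin sharpness coupled to the same latent: higher Th2 -> sharper
    # margin, so sharpness and rim brightening move together.
    # `margin_width_mm` is the 10-90% transition distance; the logistic
    # scale parameter is width / (2 ln 9).
    w <- config$margin_width_mm * exp(-0.02 * config$coupling_beta * th2)
    s_margin <- w / (2 * log(9))
    ramp <- 1 / (1 + exp(d_out / s_margin))

    vol <- config$background_hu +
      (plateau + texture - config$background_hu) * ramp
    roi <- volume_roi(vol, mask, sp)
    attr(roi, "sample_id") <- as.character(state$sample_id)
    attr(roi, "margin_width_mm") <- w
    attr(roi, "margin_sigma_mm") <- s_margin
    roi
  })
}

#' Generate a full synthetic cohort of phantoms
#'
#' @param config a [phantom_config()].
#' @param states optional tibble of latent states; defaults to
#'   [sample_latent_states()] drawn under the config seed.
#' @return A list with `config`, `states` (tibble) and `volumes` (named list
#'   of [volume_roi()]).
#' @export
generate_cohort <- function(config, states = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(states)) {
    states <- sample_latent_states(config$n_samples, config$seed)
  }
  vols <- lapply(seq_len(nrow(states)), function(i) {
    generate_phantom(config, states[i, ])
  })
  names(vols) <- states$sample_id
  list(config = config, states = states, volumes = vols)
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' Writes one image and one mask per sample and a CSV manifest with the
#' sample ids, file paths and latent immune levels.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(cohort$states$sample_id, function(sid) {
    ip <- file.path(dir, paste0(sid, "_image.nii.gz"))
    mp <- file.path(dir, paste0(sid, "_mask.nii.gz"))
    write_volume_roi(cohort$volumes[[sid]], ip, mp)
    tibble::tibble(sample_id = sid, image = ip, mask = mp)
  })
  manifest <- dplyr::left_join(dplyr::bind_rows(rows), cohort$states,
                               by = "sample_id")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
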