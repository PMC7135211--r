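# Small, fast phantom configuration used throughout this file.
small_cfg <- function(...) {
  phantom_config(grid_shape = c(26L, 26L, 26L), tumor_radius_mm = 8,
                 ...)
}

test_that("phantom_config validates geometry and names the offending axis", {
  expect_s3_class(small_cfg(), "phantom_config")
  expect_error(phantom_config(grid_shape = c(20L, 40L, 40L),
                              tumor_radius_mm = 14),
               "axis 1")
  expect_error(small_cfg(margin_width_mm = -1), "margin_width_mm")
  expect_error(small_cfg(noise_sd_hu = -2), "noise_sd_hu")
  expect_error(small_cfg(spacing_mm = 0), "spacing_mm")
})

test_that("phantom generation is deterministic given config and state", {
  cfg <- small_cfg(n_samples = 2L, seed = 9L)
  states <- sample_latent_states(2, seed = 9L)
  a <- generate_phantom(cfg, states[1, ])
  b <- generate_phantom(cfg, states[1, ])
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$mask, b$mask)
  # different samples differ
  c2 <- generate_phantom(cfg, states[2, ])
  expect_false(identical(a$intensities, c2$intensities))
})

test_that("noiseless phantom matches its plateau model in the deep core", {
  cfg <- small_cfg(noise_sd_hu = 0, rim_mean_hu = 60, core_mean_hu = 30,
                   coupling_beta = 0, eccentricity = 0, seed = 2L)
  st <- list(sample_id = "S1", th1_level = 0, th2_level = 0, ctl_level = 0)
  roi <- generate_phantom(cfg, st)
  # voxels more than 6 mm inside the surface sit at the core mean, up to
  # the documented exponential rim tail: (rim - core) * exp(-d / 2 mm)
  # bounds the residual at 30 * exp(-3) = 1.49 HU for d = 6 mm
  inner <- rimmune:::erode_mask_mm(roi$mask, roi$spacing_mm, 6)
  expect_lt(max(abs(roi$intensities[inner] - 30)), 1.6)
  # more than 6 mm outside the tumor the field is at background
  deep_out <- rimmune:::erode_mask_mm(!roi$mask, roi$spacing_mm, 6)
  expect_gt(sum(deep_out), 0)
  expect_lt(max(abs(roi$intensities[deep_out] - (-800))), 1)
})

test_that("rim mean drives the outer shell and mask matches the ellipsoid", {
  # the outer-shell mean is not directly comparable to the core (the
  # logistic ramp pulls boundary voxels toward background), so compare two
  # phantoms that differ only in rim mean: the shell must track it
  st <- list(sample_id = "S1", th1_level = 0, th2_level = 0, ctl_level = 0)
  mk <- function(rim) {
    cfg <- small_cfg(noise_sd_hu = 0, rim_mean_hu = rim, core_mean_hu = 20,
                     eccentricity = 0, seed = 5L)
    generate_phantom(cfg, st)
  }
  hi <- mk(80)
  lo <- mk(20)
  rs <- decompose_regions(hi, rim_depth_mm = 2, seed = 1)
  gain <- mean(hi$intensities[rs$outer_mask]) -
    mean(lo$intensities[rs$outer_mask])
  expect_gt(gain, 20)   # a good share of the 60 HU rim contrast
  # and the deep core agrees up to the exponential rim tail, bounded by
  # the 60 HU rim contrast times exp(-6 / 2) = 2.99 HU at 6 mm depth
  deep <- rimmune:::erode_mask_mm(hi$mask, hi$spacing_mm, 6)
  expect_lt(max(abs(hi$intensities[deep] - lo$intensities[deep])), 3)
  # mask volume close to the analytic sphere volume
  vol <- sum(hi$mask) * prod(hi$spacing_mm)
  expect_lt(abs(vol - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.15)
})

test_that("coupling shifts the rim by beta HU per unit th2 latent", {
  base <- small_cfg(noise_sd_hu = 0, eccentricity = 0, seed = 3L)
  cp <- small_cfg(noise_sd_hu = 0, eccentricity = 0, seed = 3L,
                  coupling_beta = 20)
  st <- list(sample_id = "S1", th1_level = 0, th2_level = 1.5, ctl_level = 0)
  r0 <- generate_phantom(base, st)
  r1 <- generate_phantom(cp, st)
  rs0 <- decompose_regions(r0, seed = 1)
  rs1 <- decompose_regions(r1, seed = 1)
  gain <- mean(r1$intensities[rs1$outer_mask]) -
    mean(r0$intensities[rs0$outer_mask])
  # outer-shell mean rises with the planted coupling; the full 30 HU
  # (beta * th2) appears right at the surface, the shell average sees most
  # of it plus the sharper margin's effect
  expect_gt(gain, 10)
  # the margin narrows monotonically with th2 under positive coupling
  expect_lt(attr(r1, "margin_width_mm"), attr(r0, "margin_width_mm"))
  # and the core is untouched up to the exponential rim tail, bounded by
  # beta * th2 * exp(-6 / 2) = 30 * exp(-3) = 1.49 HU at 6 mm depth
  deep0 <- rimmune:::erode_mask_mm(r0$mask, r0$spacing_mm, 6)
  expect_lt(max(abs(r1$intensities[deep0] - r0$intensities[deep0])), 1.6)
})

test_that("image-immune association is monotone in coupling_beta", {
  betas <- c(0, 12, 36)
  states <- sample_latent_states(24, seed = 21L)
  cors <- vapply(betas, function(b) {
    cfg <- small_cfg(n_samples = 24L, seed = 21L, coupling_beta = b)
    co <- generate_cohort(cfg, states)
    dm <- vapply(co$volumes, function(v) {
      mean(decompose_regions(v, seed = 1)$delta_values)
    }, numeric(1))
    cor(dm, states$th2_level)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_lt(abs(cors[1]), 0.5)   # null coupling: no systematic association
  expect_gt(cors[3], 0.7)        # strong coupling: clear association
})

test_that("latent states are reproducible and standard-normal-ish", {
  s1 <- sample_latent_states(500, seed = 1)
  s2 <- sample_latent_states(500, seed = 1)
  expect_identical(s1, s2)
  expect_lt(abs(mean(s1$th2_level)), 0.2)
  expect_lt(abs(sd(s1$th2_level) - 1), 0.15)
  expect_false(identical(s1$th1_level, s1$th2_level))
})

test_that("gaussian smoothing preserves constants and the mean", {
  x <- array(7, dim = c(8, 8, 8))
  expect_equal(rimmune:::gaussian_smooth3d(x, 2, c(1, 1, 1)), x)
  set.seed(2)
  y <- array(rnorm(8^3), dim = c(8, 8, 8))
  ys <- rimmune:::gaussian_smooth3d(y, 1.5, c(1, 1, 1))
  expect_lt(sd(ys), sd(y))          # smoothing shrinks variance
  expect_lt(abs(mean(ys) - mean(y)), 0.05)
})

test_that("write_cohort emits readable NIfTI pairs and a manifest", {
  cfg <- small_cfg(n_samples = 2L, seed = 4L)
  co <- generate_cohort(cfg)
  dir <- tempfile("cohort_")
  mf <- write_cohort(co, dir)
  expect_true(all(file.exists(mf$image, mf$mask)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_volume_roi(mf$image[1], mf$mask[1])
  expect_equal(back$intensities, co$volumes[[1]]$intensities,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$mask, co$volumes[[1]]$mask)
})
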