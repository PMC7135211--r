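#' The 239-feature radiomic catalog
#'
#' Builds the default feature manifest: 3 physical, 59 histogram-based, 10
#' shape, 95 local texture, 63 Laplacian-of-Gaussian filter, 3 fractal and 6
#' sigmoid margin features (239 in total). Histogram features are computed
#' on five intensity regions: the whole tumor (`total`), an eroded core
#' (`inner`), the peritumoral shell (`outer`), paired outer-minus-inner
#' differences (`delta`) and a seeded subsample of those (`deltaS`).
#'
#' @param glcm_distances voxel distances for the co-occurrence family.
#' @param log_sigmas_mm Laplacian-of-Gaussian scales (mm).
#' @return A tibble with columns `feature_id`, `group`, `region`, `params`
#'   satisfying the census \{physical: 3, histogram: 59, shape: 10,
#'   local: 95, log_filter: 63, fractal: 3, sigmoid: 6\}.
#' @export
feature_catalog <- function(glcm_distances = c(1L, 2L),
                            log_sigmas_mm = seq(0.5, 3.5, by = 0.5)) {
  hist_stats <- c("mean", "sd", "variance", "skewness", "kurtosis",
                  "median", "min", "max", "entropy", "uniformity", "iqr")
  regions <- c("total", "inner", "outer", "delta", "deltaS")
  hist_rows <- tidyr::expand_grid(stat = hist_stats, region = regions) |>
    dplyr::transmute(
      feature_id = paste0("hist_", .data$stat, "_", .data$region),
      group = "histogram", region = .data$region, params = .data$stat
    )
  pct_rows <- tibble::tibble(
    feature_id = paste0("hist_p", c(10, 25, 75, 90), "_total"),
    group = "histogram", region = "total",
    params = paste0("p", c(10, 25, 75, 90))
  )

  phys_rows <- tibble::tibble(
    feature_id = c("phys_volume_mm3", "phys_mass", "phys_max_axial_area_mm2"),
    group = "physical", region = "total",
    params = c("volume", "mass_surrogate", "max_axial_area")
  )

  shape_stats <- c("volume", "surface_area", "surface_to_volume",
                   "sphericity", "compactness1", "compactness2",
                   "spherical_disproportion", "max_diameter_3d",
                   "elongation", "flatness")
  shape_rows <- tibble::tibble(
    feature_id = paste0("shape_", shape_stats),
    group = "shape", region = "n/a", params = shape_stats
  )

  glcm_rows <- tidyr::expand_grid(stat = glcm_stat_names(),
                                  d = glcm_distances) |>
    dplyr::transmute(
      feature_id = paste0("glcm_", .data$stat, "_d", .data$d),
      group = "local", region = "total",
      params = paste0(.data$stat, ";distance=", .data$d)
    )
  other_local <- tibble::tibble(
    feature_id = c(paste0("glrlm_", glrlm_stat_names()),
                   paste0("glszm_", glszm_stat_names()),
                   paste0("ngtdm_", ngtdm_stat_names()),
                   paste0("gldm_", gldm_stat_names())),
    group = "local", region = "total",
    params = c(glrlm_stat_names(), glszm_stat_names(),
               ngtdm_stat_names(), gldm_stat_names())
  )

  log_stats <- c("mean", "sd", "skewness", "kurtosis", "median",
                 "min", "max", "entropy", "uniformity")
  log_rows <- tidyr::expand_grid(sigma = log_sigmas_mm, stat = log_stats) |>
    dplyr::transmute(
      feature_id = sprintf("log_s%.1f_%s", .data$sigma, .data$stat),
      group = "log_filter", region = "total",
      params = sprintf("%s;sigma_mm=%.1f", .data$stat, .data$sigma)
    )

  fractal_rows <- tibble::tibble(
    feature_id = c("fractal_boundary_dim", "fractal_intensity_dim",
                   "fractal_lacunarity"),
    group = "fractal", region = "n/a",
    params = c("boundary_box_counting", "differential_box_counting",
               "gliding_box_lacunarity")
  )

  sigmoid_rows <- tidyr::expand_grid(
    param = c("amplitude", "slope", "center"),
    stat = c("mean", "sd")
  ) |>
    dplyr::transmute(
      feature_id = paste0("sigmoid_", .data$param, "_", .data$stat),
      group = "sigmoid", region = "n/a",
      params = paste0(.data$param, ";", .data$stat)
    )

  cat <- dplyr::bind_rows(phys_rows, hist_rows, pct_rows, shape_rows,
                          glcm_rows, other_local, log_rows, fractal_rows,
                          sigmoid_rows)
  validate_catalog(cat)
  cat
}

# Census expected of every catalog and every extracted feature vector.
catalog_census <- function() {
  c(physical = 3L, histogram = 59L, shape = 10L, local = 95L,
    log_filter = 63L, fractal = 3L, sigmoid = 6L)
}

validate_catalog <- function(cat) {
  if (anyDuplicated(cat$feature_id)) {
    stop("duplicate feature ids in catalog", call. = FALSE)
  }
  census <- catalog_census()
  got <- table(factor(cat$group, levels = names(census)))
  bad <- names(census)[as.integer(got) != census]
  if (length(bad) > 0) {
    stop("catalog census mismatch in group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(cat) != sum(census)) stop("catalog must have 239 entries", call. = FALSE)
  invisible(cat)
}

#' Read or write a feature catalog as YAML
#'
#' The catalog is data: editing the YAML re-aligns the manifest without code
#' changes, as long as the seven-group census is preserved.
#'
#' @param path file path.
#' @return `read_catalog_yaml()`: a validated catalog tibble.
#' @export
read_catalog_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cat <- dplyr::bind_rows(lapply(raw$features, tibble::as_tibble))
  validate_catalog(cat)
  cat
}

#' @rdname read_catalog_yaml
#' @param catalog a catalog tibble from [feature_catalog()].
#' @export
write_catalog_yaml <- function(catalog, path) {
  validate_catalog(catalog)
  yaml::write_yaml(
    list(version = 1L,
         census = as.list(catalog_census()),
         features = purrr::transpose(as.list(catalog))),
    path
  )
  invisible(path)
}
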