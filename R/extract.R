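#' Extract the full radiomic feature vector from one volume
#'
#' Runs every feature family in the catalog against a [volume_roi()] and
#' returns one row per sample: 239 features spanning physical, histogram
#' (on the total/inner/outer/delta/deltaS regions), shape, local texture
#' (GLCM at the catalog distances, GLRLM, GLSZM, NGTDM, GLDM),
#' Laplacian-of-Gaussian, fractal and sigmoid margin groups.
#'
#' Missing values can legitimately occur (zero-variance moments,
#' non-converged margin fits, short fractal ladders) and are left as `NA`
#' for downstream KNN imputation; any other non-finite value aborts with the
#' offending feature named.
#'
#' @param roi a [volume_roi()].
#' @param catalog feature manifest from [feature_catalog()].
#' @param seed RNG seed for the delta pairing/subsampling and margin profile
#'   sampling.
#' @param sample_id identifier for the output row; defaults to the volume's
#'   `sample_id` attribute.
#' @param rim_depth_mm erosion depth separating inner core from outer rim.
#' @param subsample_frac deltaS subsample fraction.
#' @param levels gray levels for texture discretization.
#' @param n_profiles,profile_len_mm margin profile sampling controls.
#' @return A one-row tibble: `sample_id` plus one column per catalog entry.
#' @export
extract_features <- function(roi, catalog = feature_catalog(), seed = 1L,
                             sample_id = NULL, rim_depth_mm = 2,
                             subsample_frac = 0.5, levels = 32L,
                             n_profiles = 30L, profile_len_mm = 8) {
  stopifnot(inherits(roi, "volume_roi"))
  validate_catalog(catalog)
  sample_id <- sample_id %||% attr(roi, "sample_id") %||% "sample"

  regions <- decompose_regions(roi, rim_depth_mm = rim_depth_mm,
                               subsample_frac = subsample_frac, seed = seed)
  region_values <- list(
    total = roi$intensities[roi$mask],
    inner = roi$intensities[regions$inner_mask],
    outer = roi$intensities[regions$outer_mask],
    delta = regions$delta_values,
    deltaS = regions$deltaS_values
  )

  vals <- c(
    setNames(physical_features(roi),
             c("phys_volume_mm3", "phys_mass", "phys_max_axial_area_mm2")),
    unlist(lapply(names(region_values), function(rg) {
      h <- histogram_features(region_values[[rg]])
      setNames(h, paste0("hist_", names(h), "_", rg))
    })),
    setNames(percentile_features(region_values$total),
             paste0("hist_", c("p10", "p25", "p75", "p90"), "_total")),
    local({
      sf <- shape_features(roi$mask, roi$spacing_mm)
      setNames(sf, paste0("shape_", names(sf)))
    }),
    local_features(roi, catalog, levels = levels),
    log_filter_features(roi, sigmas_mm = catalog_log_sigmas(catalog)),
    setNames(fractal_features(roi), paste0("fractal_",
                                           c("boundary_dim", "intensity_dim",
                                             "lacunarity"))),
    setNames(
      sigmoid_features(roi, n_profiles = n_profiles,
                       profile_len_mm = profile_len_mm, seed = seed),
      paste0("sigmoid_", c("amplitude_mean", "amplitude_sd", "slope_mean",
                           "slope_sd", "center_mean", "center_sd"))
    )
  )

  missing_ids <- setdiff(catalog$feature_id, names(vals))
  if (length(missing_ids) > 0) {
    stop("extraction produced no value for: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  vals <- vals[catalog$feature_id]
  bad <- names(vals)[!is.na(vals) & !is.finite(vals)]
  if (length(bad) > 0) {
    stop("non-finite feature value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                   tibble::as_tibble(as.list(vals)))
}

catalog_log_sigmas <- function(catalog) {
  ids <- catalog$feature_id[catalog$group == "log_filter"]
  sort(unique(as.numeric(sub("^log_s([0-9.]+)_.*$", "\\1", ids))))
}

catalog_glcm_distances <- function(catalog) {
  ids <- catalog$feature_id[grepl("^glcm_", catalog$feature_id)]
  sort(unique(as.integer(sub("^.*_d([0-9]+)$", "\\1", ids))))
}

#' All local-texture features (GLCM, GLRLM, GLSZM, NGTDM, GLDM)
#'
#' @param roi a [volume_roi()].
#' @param catalog feature manifest (provides the GLCM distance grid).
#' @param levels gray levels for discretization.
#' @return Named numeric vector of 95 features.
#' @export
local_features <- function(roi, catalog = feature_catalog(), levels = 32L) {
  glcm_part <- unlist(lapply(catalog_glcm_distances(catalog), function(d) {
    f <- glcm_features(glcm_build(roi, levels = levels, distance_voxels = d))
    setNames(f, paste0("glcm_", names(f), "_d", d))
  }))
  c(glcm_part,
    setNames(glrlm_features(roi, levels), paste0("glrlm_", glrlm_stat_names())),
    setNames(glszm_features(roi, levels), paste0("glszm_", glszm_stat_names())),
    setNames(ngtdm_features(roi, levels), paste0("ngtdm_", ngtdm_stat_names())),
    setNames(gldm_features(roi, levels), paste0("gldm_", gldm_stat_names())))
}

#' Extract features for a whole cohort
#'
#' @param volumes named list of [volume_roi()] (names are sample ids).
#' @param catalog feature manifest.
#' @param seed RNG seed (shared across samples so subsampling is
#'   deterministic per volume).
#' @param ... passed to [extract_features()].
#' @return A tibble, one row per sample: `sample_id` + 239 feature columns.
#' @export
extract_cohort <- function(volumes, catalog = feature_catalog(), seed = 1L,
                           ...) {
  rows <- purrr::imap(volumes, function(v, nm) {
    extract_features(v, catalog = catalog, seed = seed, sample_id = nm, ...)
  })
  dplyr::bind_rows(rows)
}

#' Write/read a feature table as CSV with a sidecar census JSON
#'
#' @param features tibble from [extract_cohort()].
#' @param path CSV path; the sidecar JSON is written next to it.
#' @param catalog the catalog used for extraction.
#' @param seed the extraction seed, recorded in the sidecar.
#' @return The CSV path, invisibly.
#' @export
write_feature_table <- function(features, path, catalog = feature_catalog(),
                                seed = NA_integer_) {
  readr::write_csv(features, path)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(census = as.list(catalog_census()), n_features = nrow(catalog),
         n_samples = nrow(features), seed = seed),
    sidecar, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = readr::col_character(),
                                          .default = readr::col_double()))
}
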