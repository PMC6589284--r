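# Assembly of the full 46-descriptor vector and the batch feature table.

#' Names of the 46 descriptors, in table order
#'
#' @param prefixed prepend the column index (`f01_...`) as used in feature
#'   table CSVs.
#' @return character vector of length 46.
#' @export
feature_names <- function(prefixed = FALSE) {
  nm <- c(
    "nc_ratio", "form_factor", "roundness", "eccentricity", "compactness",
    "symmetry", "hand_mirror",
    "fractal_nucleus", "contour_var_nucleus", "contour_skew_nucleus",
    "contour_kurt_nucleus",
    "fractal_cell", "contour_var_cell", "contour_skew_cell",
    "contour_kurt_cell",
    "haar_mean_A", "haar_mean_H", "haar_mean_V",
    "haar_var_A", "haar_var_H", "haar_var_V",
    "glcm_contrast", "glcm_correlation", "glcm_homogeneity", "glcm_energy",
    "glcm_entropy",
    "fft_mean", "fft_sd", "fft_skew", "fft_kurt",
    "ifft_mean", "ifft_sd", "ifft_skew", "ifft_kurt",
    "nuc_mean_R", "nuc_mean_G", "nuc_mean_B",
    "nuc_mean_H", "nuc_mean_S", "nuc_mean_V",
    "cyto_mean_R", "cyto_mean_G", "cyto_mean_B",
    "cyto_mean_H", "cyto_mean_S", "cyto_mean_V"
  )
  if (prefixed) paste0(sprintf("f%02d_", seq_along(nm)), nm) else nm
}

#' Options for feature extraction
#'
#' Bundles the numerical conventions of the descriptor engine so a run can
#' be replayed exactly; written as a JSON sidecar next to feature tables.
#'
#' @param haar_level Haar decomposition level.
#' @param glcm_levels gray levels for the co-occurrence matrix.
#' @param conventional_form_factor use `4*pi*A/P^2` instead of the literal
#'   `A/P`.
#' @return a `feature_options` list.
#' @export
feature_options <- function(haar_level = 1, glcm_levels = 8,
                            conventional_form_factor = FALSE) {
  structure(
    list(haar_level = haar_level, glcm_levels = glcm_levels,
         conventional_form_factor = conventional_form_factor,
         grayscale = "0.299R + 0.587G + 0.114B",
         hsv_scale = "[0,1], achromatic hue = 0",
         perimeter = "chain steps, diagonals weighted sqrt(2)",
         moments = "population; kurtosis non-excess",
         patch_fill = "nucleus mean intensity outside mask",
         fourier = "unnormalized forward, 1/N^2 inverse of magnitude-only spectrum",
         box_sizes = c(2, 4, 8, 16, 32, 64)),
    class = "feature_options"
  )
}

with_feature_range <- function(range, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("features %s: %s", range, conditionMessage(e)), call. = FALSE)
  })
}

#' Extract the full 46-descriptor vector for one sample
#'
#' @param sample a [labeled_sample()].
#' @param options a [feature_options()].
#' @return named numeric vector of length 46, in table order; deterministic
#'   for a fixed input.
#' @export
extract_all <- function(sample, options = feature_options()) {
  stopifnot(inherits(sample, "labeled_sample"))
  nuc_tr <- with_feature_range("9-11", contour_trace(sample$nucleus_mask))
  cell_tr <- with_feature_range("13-15", contour_trace(sample$cell_mask))
  v <- c(
    with_feature_range("1-5",
      region_geometry(sample, options$conventional_form_factor)),
    symmetry = with_feature_range("6", shape_symmetry(sample$nucleus_mask)),
    hand_mirror = with_feature_range("7", hand_mirror_ratio(sample)),
    fractal_nucleus = with_feature_range("8",
      fractal_dimension(sample$nucleus_mask)),
    stats::setNames(with_feature_range("9-11", contour_moments(nuc_tr)),
      c("contour_var_nucleus", "contour_skew_nucleus", "contour_kurt_nucleus")),
    fractal_cell = with_feature_range("12",
      fractal_dimension(sample$cell_mask)),
    stats::setNames(with_feature_range("13-15", contour_moments(cell_tr)),
      c("contour_var_cell", "contour_skew_cell", "contour_kurt_cell")),
    with_feature_range("16-21", haar_features(sample, options$haar_level)),
    with_feature_range("22-26", haralick_features(sample, options$glcm_levels)),
    with_feature_range("27-34", fourier_features(sample)),
    with_feature_range("35-46", color_features(sample))
  )
  stopifnot(identical(names(v), feature_names()), all(is.finite(v)))
  v
}

#' Extract a feature table for a batch of samples
#'
#' @param samples list of [labeled_sample()] objects.
#' @param options a [feature_options()].
#' @return data frame with columns `source_id`, `label` and `f01_...` to
#'   `f46_...`, one row per sample.
#' @export
extract_features <- function(samples, options = feature_options()) {
  mat <- t(vapply(samples, function(s) extract_all(s, options),
                  numeric(46)))
  colnames(mat) <- feature_names(prefixed = TRUE)
  cbind(
    data.frame(
      source_id = vapply(samples, `[[`, "", "source_id"),
      label = vapply(samples, `[[`, "", "label"),
      stringsAsFactors = FALSE
    ),
    as.data.frame(mat)
  )
}

#' Write a feature table CSV with a JSON sidecar of extraction options
#'
#' @param table data frame from [extract_features()].
#' @param path output CSV path; the sidecar is written as `<path>.json`.
#' @param options the [feature_options()] used.
#' @export
write_feature_table <- function(table, path, options = feature_options()) {
  utils::write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(unclass(options), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
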