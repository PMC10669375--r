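# Mask/report output and the YAML configuration schema.

#' Default pipeline configuration
#'
#' One flat mapping holding every tunable threshold and tolerance of the
#' pipeline, with the defaults documented in the methods vignette.  A user
#' YAML file (see [load_config()]) overrides individual keys.
#'
#' Gaussian widths in `kernel_widths` follow the standard-deviation
#' convention in mm (not FWHM).  The per-kernel width list is site data: it
#' must be calibrated against the scanner fleet at hand, so only a small
#' illustrative set ships with the package and unknown kernels fall back to
#' `default_kernel_width`.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    sentinel_hu = -1500,
    # kernel-conditional resolution harmonization
    kernel_widths = list(SYNTHETIC = 0, STANDARD = 0.4, LUNG = 0.7,
                         BONE = 0.8, B70f = 0.8, FC51 = 0.7),
    default_kernel_width = 0,
    target_resolution_mm = 0.529,  # recorded as metadata; no regridding
    # anatomy
    lung_threshold_hu = -320,
    lung_closing_radius_vox = 3,
    lung_min_fraction = 0.05,
    trachea_top_fraction = 0.15,
    trachea_area_mm2 = c(20, 500),
    trachea_circularity_min = 0.4,
    airway_grow_offset_hu = 150,
    airway_leak_area_factor = 3,
    airway_leak_median_slices = 10,
    vessel_threshold_hu = -500,
    vessel_min_width_vox = 2,
    # air background / references
    background_hist_lo_hu = -1400,
    background_hist_hi_hu = 200,
    background_scan_from_hu = -1024,
    background_min_count_frac = 0.01,
    background_prominence_frac = 0.20,
    background_max_hu = -800,
    airway_min_voxels_per_slice = 10,
    # parenchyma mode filter
    window_diameter_mm = 35,
    window_sigma_mm = 8.75,
    hist_upper_hu = -500,
    hist_lower_offset_hu = 25,
    hist_smooth_sd_hu = 10,
    map_stride = 4L,
    availability_min_weight_frac = 0.05,
    # cysts
    cyst_min_volume_mm3 = 0
  )
}

#' Load a pipeline configuration file
#'
#' Reads a schema-versioned YAML file and merges it over [default_config()].
#' Unknown keys produce a warning (they are carried through untouched);
#' malformed values are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$schema_version) && user$schema_version != cfg$schema_version)
    stop("unsupported configuration schema_version: ", user$schema_version)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  kw <- unlist(cfg$kernel_widths)
  if (length(kw) && (any(!is.finite(kw)) || any(kw < 0)))
    stop("kernel_widths must be non-negative finite Gaussian widths in mm")
  if (cfg$default_kernel_width < 0) stop("default_kernel_width must be >= 0")
  scalars <- c("lung_threshold_hu", "vessel_threshold_hu", "hist_upper_hu",
               "hist_lower_offset_hu", "hist_smooth_sd_hu", "window_sigma_mm",
               "window_diameter_mm")
  for (s in scalars)
    if (!is.numeric(cfg[[s]]) || length(cfg[[s]]) != 1 || !is.finite(cfg[[s]]))
      stop("configuration value ", s, " must be a single finite number")
  if (cfg$window_diameter_mm <= 0 || cfg$window_sigma_mm <= 0)
    stop("histogram window geometry must be positive")
  if (cfg$map_stride < 1) stop("map_stride must be >= 1")
  if (cfg$availability_min_weight_frac < 0 || cfg$availability_min_weight_frac > 1)
    stop("availability_min_weight_frac must be in [0, 1]")
  invisible(cfg)
}

.mask_affine <- function(mask) {
  # encode spacing and the superior->inferior slice order (z decreasing)
  diag(c(mask$spacing[1], mask$spacing[2], -mask$spacing[3], 1))
}

#' Write a binary mask as compressed NIfTI
#'
#' @param mask a [mask_volume].
#' @param path output path (`.nii.gz`).
#' @param reference optional [ct_volume]; when given, the mask grid must
#'   match it.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path, reference = NULL) {
  stopifnot(inherits(mask, "mask_volume"))
  if (!is.null(reference)) assert_same_grid(mask, reference, "mask and reference")
  arr <- array(as.integer(mask$voxels), dim_of(mask))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- mask$spacing
  RNifti::`qform<-`(nii, structure(.mask_affine(mask), code = 1L))
  RNifti::writeNifti(nii, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path NIfTI file.
#' @param grid [ct_volume] (or mask) supplying the expected geometry.
#' @param label mask label, see [mask_volume()].
#' @export
read_mask <- function(path, grid, label = "lung") {
  nii <- RNifti::readNifti(path)
  arr <- array(as.integer(nii), dim(nii))
  if (!all(arr %in% c(0L, 1L))) stop("mask file is not binary: ", path)
  mask_volume(array(arr == 1L, dim(arr)), grid, label)
}

#' Read / write cyst-score tables
#'
#' CSV with columns `patient_id, exam_date, years_from_first, cyst_score,
#' lung_volume_ml, cyst_volume_ml`.
#'
#' @param scores data frame with the columns above.
#' @param path CSV path.
#' @export
write_score_table <- function(scores, path) {
  need <- c("patient_id", "exam_date", "years_from_first", "cyst_score",
            "lung_volume_ml", "cyst_volume_ml")
  missing <- setdiff(need, names(scores))
  if (length(missing)) stop("score table lacks columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(scores[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$exam_date <- as.Date(df$exam_date)
  df
}
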