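# Voxelwise cyst classification and the cyst score.
#
# A voxel inside the lungs (airways excluded) is cystic when its
# radiodensity falls below the midpoint of the local non-cystic parenchyma
# level and the per-slice intra-lung air reference:
#
#     I(x,y,z) < (I_p(x,y,z) + I_air(z)) / 2        where I_p exists,
#     I(x,y,z) <  I_air(z) + 25 HU                  where it does not
#                                                   (centres of very large
#                                                   cysts, air voids).
#
# The cyst score is the cystic fraction of the lung volume.

#' Classify cystic voxels with the adaptive local threshold
#'
#' @param vol a (harmonized) [ct_volume].
#' @param lung,airway [mask_volume]s.
#' @param pmap a `parenchyma_map` from [parenchyma_density_map()].
#' @param ref an `air_reference`.
#' @param config configuration list; `hist_lower_offset_hu` is the +25 HU
#'   fallback margin, `cyst_min_volume_mm3 > 0` enables an optional
#'   minimum-component-volume filter (off by default).
#' @return a [mask_volume] with label `"cyst"`.
#' @export
classify_cysts <- function(vol, lung, airway, pmap, ref,
                           config = default_config()) {
  stopifnot(is_ct_volume(vol), inherits(pmap, "parenchyma_map"),
            inherits(ref, "air_reference"))
  assert_same_grid(vol, lung, "volume and lung mask")
  assert_same_grid(vol, airway, "volume and airway mask")
  d <- dim(vol$voxels)
  region <- lung$voxels & !airway$voxels & valid_voxels(vol)
  cyst <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    thr <- ifelse(pmap$available[, , k],
                  (pmap$values[, , k] + ref$I_air[k]) / 2,
                  ref$I_air[k] + config$hist_lower_offset_hu)
    cyst[, , k] <- region[, , k] & vol$voxels[, , k] < thr
  }
  if (config$cyst_min_volume_mm3 > 0) {
    lab <- cpp_label3d(cyst, d, 26L)
    keep <- which(tabulate(lab) * voxel_volume_mm3(vol) >=
                    config$cyst_min_volume_mm3)
    cyst <- array(lab %in% keep, d)
  }
  mask_volume(cyst, vol, "cyst")
}

#' Fixed global-threshold cyst classification (baseline)
#'
#' Stand-in for operator-adjusted semi-automated scoring: every
#' lung-minus-airway voxel below one global radiodensity threshold is
#' called cystic.  Used as the comparison baseline in robustness analyses.
#'
#' @param vol a [ct_volume].
#' @param lung,airway [mask_volume]s.
#' @param threshold global threshold in HU, inside (-1024, -500).
#' @return a [mask_volume] with label `"cyst"`.
#' @export
classify_cysts_global <- function(vol, lung, airway, threshold) {
  stopifnot(is_ct_volume(vol))
  if (threshold <= -1024 || threshold >= -500)
    stop("global cyst threshold must lie in (-1024, -500) HU")
  assert_same_grid(vol, lung, "volume and lung mask")
  region <- lung$voxels & !airway$voxels & valid_voxels(vol)
  mask_volume(region & vol$voxels < threshold, vol, "cyst")
}

#' Cyst score from masks
#'
#' Volumes are voxel counts times the voxel volume; the score is the total
#' cystic volume divided by the total lung volume (airways excluded from
#' both numerator and denominator).
#'
#' @param cyst,lung,airway [mask_volume]s on one grid.
#' @return object of class `cyst_result`: `cyst_mask`, `lung_volume_ml`,
#'   `cyst_volume_ml`, `cyst_score` (fraction in `[0, 1]`).
#' @export
cyst_score <- function(cyst, lung, airway) {
  assert_same_grid(cyst, lung, "cyst and lung masks")
  assert_same_grid(cyst, airway, "cyst and airway masks")
  vv <- voxel_volume_mm3(cyst)
  lung_vox <- lung$voxels & !airway$voxels
  if (!any(lung_vox)) stop("lung volume is zero")
  cyst_vox <- cyst$voxels & lung_vox
  structure(list(cyst_mask = cyst,
                 lung_volume_ml = sum(lung_vox) * vv / 1000,
                 cyst_volume_ml = sum(cyst_vox) * vv / 1000,
                 cyst_score = sum(cyst_vox) / sum(lung_vox)),
            class = "cyst_result")
}

#' @export
print.cyst_result <- function(x, ...) {
  cat(sprintf(
    "cyst_result: lung %.1f mL, cysts %.1f mL, cyst score %.4f (%.2f%%)\n",
    x$lung_volume_ml, x$cyst_volume_ml, x$cyst_score, 100 * x$cyst_score))
  invisible(x)
}
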