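#' Calibrated CT volume
#'
#' Container for a 3-D chest CT scalar field calibrated to Hounsfield units,
#' together with its voxel geometry and scan metadata.  The array is indexed
#' `[row, column, slice]`; rows run anterior to posterior, columns left to
#' right, and slice index 1 is the most superior section (`slice_z` therefore
#' decreases with slice index, matching the patient z axis which points
#' towards the head).
#'
#' Voxels more negative than `sentinel_hu` are treated as field-of-view
#' padding (scanners commonly write -2048 or -3024 outside the reconstruction
#' circle).  They are flagged and excluded from every histogram and filter
#' support downstream, where they would otherwise masquerade as a spurious
#' density peak below the air background.
#'
#' @param voxels 3-D numeric array of radiodensities (HU).
#' @param spacing numeric length 3: row, column and slice spacing in mm, all
#'   positive.
#' @param slice_z numeric vector of per-slice axial positions (mm, patient
#'   coordinates).  Must be strictly monotonic; it is normalized so that
#'   index 1 is the most superior slice.
#' @param kernel reconstruction-kernel identifier (string; `""` if unknown).
#' @param sentinel_hu padding cutoff in HU; voxels `<= sentinel_hu` are
#'   flagged as outside the field of view.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, slice_z = NULL, kernel = "",
                      sentinel_hu = -1500) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  storage.mode(voxels) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (row, column, slice mm)")
  nz <- dim(voxels)[3]
  if (is.null(slice_z)) slice_z <- -(seq_len(nz) - 1) * spacing[3]
  slice_z <- as.numeric(slice_z)
  if (length(slice_z) != nz) stop("slice_z length must equal the slice count")
  dz <- diff(slice_z)
  if (nz > 1 && !(all(dz > 0) || all(dz < 0)))
    stop("slice_z must be strictly monotonic")
  # canonical order: index 1 = most superior = largest patient z
  if (nz > 1 && dz[1] > 0) {
    voxels <- voxels[, , nz:1, drop = FALSE]
    slice_z <- rev(slice_z)
  }
  if (any(!is.finite(voxels))) stop("voxel values must be finite")
  sentinel <- voxels <= sentinel_hu
  structure(
    list(voxels = voxels, spacing = spacing, slice_z = slice_z,
         kernel = as.character(kernel)[1],
         sentinel = if (any(sentinel)) sentinel else NULL,
         sentinel_hu = sentinel_hu),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  kernel: %s   HU range: [%.0f, %.0f]   padding voxels: %d\n",
              if (nzchar(x$kernel)) x$kernel else "<none>",
              min(x$voxels), max(x$voxels),
              if (is.null(x$sentinel)) 0L else sum(x$sentinel)))
  invisible(x)
}

#' @rdname ct_volume
#' @param x object to test.
#' @export
is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Logical array of voxels usable for statistics (non-padding)
#' @param vol a [ct_volume].
#' @return logical 3-D array, `TRUE` where the voxel is inside the scanner
#'   field of view.
#' @export
valid_voxels <- function(vol) {
  if (is.null(vol$sentinel)) array(TRUE, dim(vol$voxels)) else !vol$sentinel
}

#' Binary mask on a CT grid
#'
#' A strictly binary 3-D label volume sharing the geometry of its parent
#' [ct_volume].
#'
#' @param voxels logical (or 0/1) 3-D array.
#' @param grid the parent [ct_volume] (or another `mask_volume`) providing
#'   the geometry.
#' @param label one of `"lung"`, `"airway"`, `"vessel"`, `"cyst"`, `"body"`,
#'   `"truth_cyst"`, `"truth_lung"`, `"truth_airway"`, `"truth_vessel"`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, grid, label = "lung") {
  lbl <- match.arg(label, c("lung", "airway", "vessel", "cyst", "body",
                            "truth_cyst", "truth_lung", "truth_airway",
                            "truth_vessel"))
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("mask voxels must be strictly binary")
    voxels <- array(voxels != 0, dim(voxels))
  }
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3L)
  ref <- grid_of(grid)
  if (!identical(dim(voxels), dim_of(grid)))
    stop("mask shape does not match its parent grid")
  structure(list(voxels = voxels, spacing = ref$spacing, slice_z = ref$slice_z,
                 label = lbl),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("mask_volume '%s': %d x %d x %d, %d voxels set (%.2f mL)\n",
              x$label, d[1], d[2], d[3], sum(x$voxels),
              sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

grid_of <- function(x) list(spacing = x$spacing, slice_z = x$slice_z)

dim_of <- function(x) dim(x$voxels)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim_of(a), dim_of(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$slice_z - b$slice_z)) < tol
}

assert_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same voxel grid", what))
  invisible(TRUE)
}

#' Voxel volume in mm^3
#' @param x a [ct_volume] or [mask_volume].
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#'
#' @param a,b [mask_volume] objects (or logical arrays) on the same grid.
#' @export
mask_dice <- function(a, b) {
  av <- if (inherits(a, "mask_volume")) a$voxels else a
  bv <- if (inherits(b, "mask_volume")) b$voxels else b
  stopifnot(identical(dim(av), dim(bv)))
  2 * sum(av & bv) / (sum(av) + sum(bv))
}

#' Sensitivity and specificity of a mask against a truth mask
#'
#' Evaluated voxelwise inside `region` (for example the lung); sensitivity is
#' the detected fraction of truth voxels, specificity the correctly rejected
#' fraction of non-truth voxels.
#'
#' @param pred,truth [mask_volume] objects or logical arrays.
#' @param region optional logical array restricting the evaluation.
#' @return named numeric vector with `sensitivity` and `specificity`.
#' @export
mask_accuracy <- function(pred, truth, region = NULL) {
  pv <- if (inherits(pred, "mask_volume")) pred$voxels else pred
  tv <- if (inherits(truth, "mask_volume")) truth$voxels else truth
  stopifnot(identical(dim(pv), dim(tv)))
  keep <- if (is.null(region)) rep(TRUE, length(pv)) else {
    rv <- if (inherits(region, "mask_volume")) region$voxels else region
    as.logical(rv)
  }
  p <- pv[keep]; t <- tv[keep]
  c(sensitivity = sum(p & t) / sum(t),
    specificity = sum(!p & !t) / sum(!t))
}
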