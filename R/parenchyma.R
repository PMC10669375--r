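# Local non-cystic parenchyma radiodensity via a Gaussian-weighted local
# smoothed-histogram mode filter.
#
# At each lung location a weighted frequency histogram of the surrounding
# in-plane radiodensities (circular window, 35 mm diameter, Gaussian
# profile) is accumulated over the range [I_air(z)+25, -500] HU - a band
# that excludes large air voids below and vessels above - smoothed with a
# 1-D Gaussian, and its dominant mode taken as the local parenchyma level
# I_p.  The mode is insensitive to small changes of the range limits,
# which is the point of using it.  Windows that see almost no in-range
# tissue (centres of cysts larger than the window, air voids) yield no
# value; availability is explicit.

.window_offsets <- function(spacing, config) {
  rad <- config$window_diameter_mm / 2
  sig <- config$window_sigma_mm
  hr <- floor(rad / spacing[1])
  hc <- floor(rad / spacing[2])
  dr <- rep(-hr:hr, times = 2 * hc + 1)
  dc <- rep(-hc:hc, each = 2 * hr + 1)
  dmm2 <- (dr * spacing[1])^2 + (dc * spacing[2])^2
  keep <- dmm2 <= rad^2
  list(dr = as.integer(dr[keep]), dc = as.integer(dc[keep]),
       w = exp(-0.5 * dmm2[keep] / sig^2))
}

#' Local smoothed-histogram mode at one voxel
#'
#' Single-point version of the filter behind [parenchyma_density_map()],
#' mainly useful for inspection and validation.
#'
#' @param vol a [ct_volume].
#' @param center integer voxel index `c(row, column, slice)`.
#' @param range HU range `c(lo, hi)` of the histogram.
#' @param exclusion optional [mask_volume] (or logical array) of pixels to
#'   exclude (airways, vessels); pixels outside `include` never contribute.
#' @param include optional [mask_volume] restricting the support (the lung);
#'   default: everywhere.
#' @param config configuration list.
#' @return HU value, or `NA` when unavailable.
#' @export
local_mode <- function(vol, center, range, exclusion = NULL, include = NULL,
                       config = default_config()) {
  stopifnot(is_ct_volume(vol), length(center) == 3)
  d <- dim(vol$voxels)
  inc <- valid_voxels(vol)[, , center[3]]
  if (!is.null(include)) {
    iv <- if (inherits(include, "mask_volume")) include$voxels else include
    inc <- inc & iv[, , center[3]]
  }
  if (!is.null(exclusion)) {
    ev <- if (inherits(exclusion, "mask_volume")) exclusion$voxels else exclusion
    inc <- inc & !ev[, , center[3]]
  }
  off <- .window_offsets(vol$spacing, config)
  res <- cpp_local_mode_slice(
    vol$voxels[, , center[3]], inc,
    matrix(TRUE, d[1], d[2]),
    as.integer(center[1]), as.integer(center[2]),
    off$dr, off$dc, off$w, sum(off$w),
    range[1], range[2],
    config$hist_smooth_sd_hu, config$availability_min_weight_frac)
  as.numeric(res$value[1, 1])
}

.bilinear_from_nodes <- function(V, A, node_r, node_c, nr, nc) {
  ir <- pmin(pmax(findInterval(seq_len(nr), node_r), 1L), length(node_r) - 1L)
  ic <- pmin(pmax(findInterval(seq_len(nc), node_c), 1L), length(node_c) - 1L)
  tr <- (seq_len(nr) - node_r[ir]) / pmax(node_r[ir + 1L] - node_r[ir], 1L)
  tc <- (seq_len(nc) - node_c[ic]) / pmax(node_c[ic + 1L] - node_c[ic], 1L)
  tr <- pmin(pmax(tr, 0), 1); tc <- pmin(pmax(tc, 0), 1)
  V00 <- V[ir, ic, drop = FALSE];      V10 <- V[ir + 1L, ic, drop = FALSE]
  V01 <- V[ir, ic + 1L, drop = FALSE]; V11 <- V[ir + 1L, ic + 1L, drop = FALSE]
  TR <- matrix(tr, nr, nc); TC <- matrix(tc, nr, nc, byrow = TRUE)
  val <- (1 - TR) * (1 - TC) * V00 + TR * (1 - TC) * V10 +
    (1 - TR) * TC * V01 + TR * TC * V11
  ok <- A[ir, ic, drop = FALSE] & A[ir + 1L, ic, drop = FALSE] &
    A[ir, ic + 1L, drop = FALSE] & A[ir + 1L, ic + 1L, drop = FALSE]
  val[!ok] <- NA_real_
  list(value = val, available = ok)
}

#' Map of local non-cystic parenchyma radiodensity
#'
#' Applies the local smoothed-histogram mode filter to every lung location
#' of every CT section, with the per-slice histogram range
#' `[I_air(z) + hist_lower_offset_hu, hist_upper_hu]` and the previously
#' segmented airways and vessels excluded from the filter support.  For
#' tractability the mode is evaluated on a coarse in-plane node grid
#' (`map_stride` pixels) and interpolated bilinearly to full resolution;
#' a full-resolution voxel is available only when all four surrounding
#' nodes are available.  `map_stride = 1` gives the exhaustive per-pixel
#' map.
#'
#' @param vol a [ct_volume].
#' @param lung,airway,vessel [mask_volume]s on the grid of `vol`.
#' @param ref an `air_reference` from [build_air_reference()].
#' @param config configuration list.
#' @return object of class `parenchyma_map`: list with `values` (3-D HU
#'   array, `NA` where unavailable) and `available` (logical array, always
#'   `FALSE` outside the lung).
#' @export
parenchyma_density_map <- function(vol, lung, airway, vessel, ref,
                                   config = default_config()) {
  stopifnot(is_ct_volume(vol), inherits(ref, "air_reference"))
  assert_same_grid(vol, lung, "volume and lung mask")
  assert_same_grid(vol, airway, "volume and airway mask")
  assert_same_grid(vol, vessel, "volume and vessel mask")
  d <- dim(vol$voxels)
  if (length(ref$I_air) != d[3]) stop("air reference does not match the volume")
  stride <- max(1L, as.integer(config$map_stride))
  node_r <- unique(c(seq(1L, d[1], by = stride), d[1]))
  node_c <- unique(c(seq(1L, d[2], by = stride), d[2]))
  off <- .window_offsets(vol$spacing, config)
  total_w <- sum(off$w)
  valid <- valid_voxels(vol)
  values <- array(NA_real_, d)
  avail <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    inc <- lung$voxels[, , k] & !airway$voxels[, , k] &
      !vessel$voxels[, , k] & valid[, , k]
    cen <- lung$voxels[, , k] & !airway$voxels[, , k]
    if (!any(cen)) next
    lo <- ref$I_air[k] + config$hist_lower_offset_hu
    hi <- config$hist_upper_hu
    res <- cpp_local_mode_slice(vol$voxels[, , k], inc, cen,
                                node_r, node_c, off$dr, off$dc, off$w,
                                total_w, lo, hi,
                                config$hist_smooth_sd_hu,
                                config$availability_min_weight_frac)
    if (stride == 1L) {
      values[, , k] <- res$value
      avail[, , k] <- res$available & cen
    } else {
      bi <- .bilinear_from_nodes(res$value, res$available,
                                 node_r, node_c, d[1], d[2])
      ok <- bi$available & cen
      v <- bi$value
      v[!ok] <- NA_real_
      values[, , k] <- v
      avail[, , k] <- ok
    }
  }
  structure(list(values = values, available = avail,
                 spacing = vol$spacing, slice_z = vol$slice_z),
            class = "parenchyma_map")
}

#' @export
print.parenchyma_map <- function(x, ...) {
  n <- sum(x$available)
  cat(sprintf("parenchyma_map: %d available voxels (%.1f%% of grid)",
              n, 100 * n / length(x$available)))
  if (n > 0)
    cat(sprintf(", median I_p %.0f HU", stats::median(x$values[x$available])))
  cat("\n")
  invisible(x)
}
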