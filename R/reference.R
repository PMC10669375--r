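# Air reference levels: the global external-air background and the
# per-slice airway / intra-lung air profiles.
#
# Pulmonary cysts are air spaces, so their radiodensity tracks both the
# scanner's external-air calibration and the superior-inferior drift seen
# inside the large airways.  The per-slice intra-lung air reference is the
# midpoint of the two:  I_air(z) = (I_airway(z) + I_background) / 2.

#' Estimate the external air background level
#'
#' Builds a frequency histogram of all non-padding voxels on integer-
#' centred 1-HU bins and scans upward from `background_scan_from_hu`
#' (-1024 HU) for the first substantial peak: a local maximum whose count
#' is at least `background_min_count_frac` of all voxels and whose
#' topographic prominence is at least `background_prominence_frac` of its
#' own height.  The estimate is refined below bin resolution by the count
#' centroid over the contiguous half-height run of the peak, which tracks
#' the peak centre to a fraction of a bin whatever the peak width (a
#' fixed-width centroid window is unstable when the air peak is many bins
#' wide).  Bins extend below the scan start so that
#' adding a constant (integer) offset to the volume shifts the estimate by
#' exactly that constant.
#'
#' @param vol a [ct_volume].
#' @param config configuration list.
#' @return background level (HU scalar).
#' @export
estimate_air_background <- function(vol, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  lo <- round(config$background_hist_lo_hu)
  hi <- round(config$background_hist_hi_hu)
  v <- vol$voxels[valid_voxels(vol)]
  idx <- floor(v + 0.5) - lo + 1  # bin centred on each integer HU
  idx <- idx[idx >= 1 & idx <= hi - lo + 1]
  counts <- tabulate(idx, nbins = hi - lo + 1)
  total <- length(v)
  centers <- lo:hi
  from <- which(centers >= round(config$background_scan_from_hu))[1]
  upto <- max(which(centers <= round(config$background_max_hu)))
  prominence <- function(i) {
    h <- counts[i]
    saddle <- function(idxs) {
      m <- h
      for (j in idxs) {
        if (counts[j] > h) return(m)  # saddle towards the higher peak
        m <- min(m, counts[j])
      }
      -Inf  # no higher peak on this side
    }
    s <- max(saddle(seq(i - 1, 1)), saddle(seq(i + 1, length(counts))))
    if (is.finite(s)) h - s else h
  }
  for (i in seq(from, upto)) {
    h <- counts[i]
    if (h < config$background_min_count_frac * total) next
    if (i > 1 && counts[i - 1] > h) next
    if (i < length(counts) && counts[i + 1] > h) next
    if (prominence(i) < config$background_prominence_frac * h) next
    l <- i; while (l > 1 && counts[l - 1] >= 0.5 * h) l <- l - 1
    r <- i; while (r < length(counts) && counts[r + 1] >= 0.5 * h) r <- r + 1
    win <- l:r
    return(sum(centers[win] * counts[win]) / sum(counts[win]))
  }
  stop("no air background found: no substantial histogram peak below ",
       config$background_max_hu, " HU (cropped field of view?)")
}

#' Per-slice airway radiodensity profile
#'
#' Mean HU over the segmented airway voxels of each slice holding at least
#' `airway_min_voxels_per_slice` of them.  The most inferior valid value is
#' copied to all slices below, the most superior valid value to all slices
#' above, and interior gaps are linearly interpolated, so the profile is a
#' total function of the slice index.
#'
#' @param vol a [ct_volume].
#' @param airway airway [mask_volume].
#' @param config configuration list.
#' @return list with `profile` (numeric, one value per slice) and `valid`
#'   (logical, slices with a measured mean).
#' @export
airway_profile <- function(vol, airway, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  assert_same_grid(vol, airway, "volume and airway mask")
  if (!any(airway$voxels)) stop("airway mask is empty")
  nz <- dim(vol$voxels)[3]
  prof <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    m <- airway$voxels[, , k]
    if (sum(m) >= config$airway_min_voxels_per_slice)
      prof[k] <- mean(vol$voxels[, , k][m])
  }
  ok <- which(!is.na(prof))
  if (!length(ok)) stop("airway mask has no slice with at least ",
                        config$airway_min_voxels_per_slice, " voxels")
  filled <- prof
  if (length(ok) == 1L) {
    filled[] <- prof[ok]
  } else {
    filled <- stats::approx(ok, prof[ok], xout = seq_len(nz),
                            method = "linear", rule = 2)$y
  }
  list(profile = filled, valid = !is.na(prof))
}

#' Assemble the air reference
#'
#' @param I_background background HU from [estimate_air_background()].
#' @param profile filled profile list from [airway_profile()].
#' @return object of class `air_reference` with fields `I_background`,
#'   `I_airway` (per slice), `I_air` (per slice, the exact midpoint) and
#'   `valid` (per-slice measurement flag).
#' @export
build_air_reference <- function(I_background, profile) {
  if (is.list(profile)) {
    I_airway <- profile$profile
    valid <- profile$valid
  } else {
    I_airway <- profile
    valid <- rep(TRUE, length(profile))
  }
  if (any(!is.finite(I_airway))) stop("airway profile must be fully filled")
  if (I_background <= -1030 || I_background >= -900)
    warning("background level ", round(I_background, 1),
            " HU is outside the plausible range (-1030, -900)")
  structure(list(I_background = I_background, I_airway = I_airway,
                 I_air = (I_airway + I_background) / 2, valid = valid),
            class = "air_reference")
}

#' @export
print.air_reference <- function(x, ...) {
  cat(sprintf(
    "air_reference: I_background %.1f HU, I_airway %.1f..%.1f HU, I_air %.1f..%.1f HU (%d slices)\n",
    x$I_background, x$I_airway[1], x$I_airway[length(x$I_airway)],
    x$I_air[1], x$I_air[length(x$I_air)], length(x$I_air)))
  invisible(x)
}
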