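# Automated segmentation of the lung volume, the trachea and the large
# airways, and the bright-structure (vessel) exclusion mask.

.slice_apply <- function(arr, f) {
  out <- arr
  for (k in seq_len(dim(arr)[3])) out[, , k] <- f(arr[, , k])
  out
}

#' Segment the lungs by radiodensity thresholding
#'
#' Voxels below the lung-air threshold form candidate components in 3-D;
#' components touching the in-plane image border (external air) are
#' removed, the largest one or two remaining components are retained (two
#' lungs, possibly merged at the midline), interior holes (vessels, cyst
#' walls) are filled per slice, and the pleural boundary is smoothed by
#' morphological closing.
#'
#' @param vol a (harmonized) [ct_volume].
#' @param config configuration list; uses `lung_threshold_hu` (default
#'   -320), `lung_closing_radius_vox`, `lung_min_fraction`.
#' @return a [mask_volume] with label `"lung"`.
#' @export
segment_lungs <- function(vol, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  d <- dim(vol$voxels)
  air <- vol$voxels < config$lung_threshold_hu & valid_voxels(vol)
  lab <- cpp_label3d(air, d, 6L)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  border <- border[border > 0]
  sizes <- tabulate(lab)
  if (length(sizes)) sizes[border] <- 0L
  if (!length(sizes) || max(sizes) < config$lung_min_fraction * prod(d))
    stop("no lung found: no interior air component reaches ",
         config$lung_min_fraction * 100, "% of the volume")
  ord <- order(sizes, decreasing = TRUE)
  keep <- ord[1]
  if (length(ord) > 1 && sizes[ord[2]] >= 0.3 * sizes[ord[1]])
    keep <- c(keep, ord[2])
  mask <- array(lab %in% keep, d)
  mask <- .slice_apply(mask, function(sl)
    EBImage::fillHull(EBImage::Image(sl)) > 0)
  r <- config$lung_closing_radius_vox
  if (r > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
    mask <- .slice_apply(mask, function(sl) EBImage::closing(sl, brush) > 0)
  }
  mask_volume(mask, vol, "lung")
}

.component_stats <- function(lab2d, spacing) {
  ids <- sort(unique(as.integer(lab2d)))
  ids <- ids[ids > 0]
  lapply(ids, function(id) {
    w <- which(lab2d == id, arr.ind = TRUE)
    cen <- colMeans(w)
    rmax <- sqrt(max(((w[, 1] - cen[1]) * spacing[1])^2 +
                     ((w[, 2] - cen[2]) * spacing[2])^2))
    list(id = id, n = nrow(w), centroid = cen,
         area_mm2 = nrow(w) * spacing[1] * spacing[2],
         circularity = nrow(w) * spacing[1] * spacing[2] /
           (pi * max(rmax, spacing[1] / 2)^2),
         touches_border = any(w[, 1] %in% c(1L, nrow(lab2d))) ||
           any(w[, 2] %in% c(1L, ncol(lab2d))))
  })
}

#' Locate the trachea in the superior sections
#'
#' Within the most superior `trachea_top_fraction` of slices, finds in each
#' slice the air-like 2-D connected component nearest the axial centre with
#' an area of 20-500 mm2 and a near-circular form factor, and returns the
#' union of those components as the 3-D seed region for airway growing.
#' Slices whose candidate centroid strays more than 10 mm from the median
#' candidate centroid are dropped.
#'
#' @param vol a [ct_volume] in canonical slice order.
#' @param config configuration list.
#' @return a [mask_volume] (label `"airway"`) holding the seed voxels.
#' @export
segment_trachea <- function(vol, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  d <- dim(vol$voxels)
  ktop <- seq_len(max(1L, ceiling(config$trachea_top_fraction * d[3])))
  valid <- valid_voxels(vol)
  centre <- (d[1:2] + 1) / 2
  cands <- list()
  for (k in ktop) {
    air <- vol$voxels[, , k] < config$lung_threshold_hu & valid[, , k]
    lab <- EBImage::bwlabel(EBImage::Image(air))
    st <- .component_stats(as.matrix(lab), vol$spacing[1:2])
    st <- Filter(function(s) !s$touches_border &&
                   s$area_mm2 >= config$trachea_area_mm2[1] &&
                   s$area_mm2 <= config$trachea_area_mm2[2] &&
                   s$circularity >= config$trachea_circularity_min, st)
    if (!length(st)) next
    dc <- vapply(st, function(s) sum(((s$centroid - centre) *
                                        vol$spacing[1:2])^2), 0)
    best <- st[[which.min(dc)]]
    cands[[length(cands) + 1L]] <- list(k = k, id = best$id,
                                        centroid = best$centroid,
                                        lab = as.matrix(lab))
  }
  if (!length(cands)) stop("trachea not found in the superior sections")
  cen <- do.call(rbind, lapply(cands, `[[`, "centroid"))
  med <- apply(cen, 2, stats::median)
  keep <- sqrt(rowSums(((cen - rep(med, each = nrow(cen))) *
                          rep(vol$spacing[1:2], each = nrow(cen)))^2)) <= 10
  cands <- cands[keep]
  if (!length(cands)) stop("trachea not found in the superior sections")
  seed <- array(FALSE, d)
  for (cc in cands) seed[, , cc$k] <- cc$lab == cc$id
  mask_volume(seed, vol, "airway")
}

#' Extend the trachea seed down the large-airway tree
#'
#' Region growing from the seed over voxels below an adaptive threshold
#' (seed mean + `airway_grow_offset_hu`, clamped below the lung-air
#' threshold), proceeding slice by slice in the superior-to-inferior
#' direction; a slice's air components are accepted when they directly
#' overlap the accepted region of the slice above (diagonal-only adjacency
#' is avoided: it lets growth skip across thin airway walls where the tree
#' runs obliquely).  Leak control: when the
#' accepted cross-sectional area in a slice exceeds
#' `airway_leak_area_factor` times the running median of the previous
#' `airway_leak_median_slices` accepted slices, growth stops at that slice
#' and everything below is discarded.
#'
#' @param vol a [ct_volume].
#' @param seed seed [mask_volume] from [segment_trachea()].
#' @param config configuration list.
#' @return a [mask_volume] with label `"airway"`.
#' @export
extend_airways <- function(vol, seed, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  sv <- if (inherits(seed, "mask_volume")) seed$voxels else seed
  if (!any(sv)) stop("airway seed region is empty")
  d <- dim(vol$voxels)
  valid <- valid_voxels(vol)
  thr <- min(mean(vol$voxels[sv]) + config$airway_grow_offset_hu,
             config$lung_threshold_hu)
  acc <- array(FALSE, d)
  areas <- numeric(0)
  pixarea <- vol$spacing[1] * vol$spacing[2]
  seed_slices <- which(apply(sv, 3, any))
  grow_slice <- function(k, prev) {
    air <- vol$voxels[, , k] < thr & valid[, , k]
    if (!any(air)) return(NULL)
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(air)))
    touch <- unique(lab[prev])
    touch <- touch[touch > 0]
    if (!length(touch)) return(NULL)
    lab %in% touch & air
  }
  for (k in seed_slices) acc[, , k] <- sv[, , k]
  # consolidate seed slices to their full 2-D components
  for (k in seed_slices) {
    sl <- grow_slice(k, acc[, , k])
    if (!is.null(sl)) acc[, , k] <- matrix(sl, d[1], d[2])
    areas <- c(areas, sum(acc[, , k]) * pixarea)
  }
  k0 <- max(seed_slices)
  if (k0 < d[3]) {
    for (k in (k0 + 1L):d[3]) {
      sl <- grow_slice(k, acc[, , k - 1])
      if (is.null(sl)) break
      area <- sum(sl) * pixarea
      nlast <- min(length(areas), config$airway_leak_median_slices)
      if (nlast >= 3) {
        med <- stats::median(utils::tail(areas, nlast))
        if (area > config$airway_leak_area_factor * med) break
      }
      acc[, , k] <- matrix(sl, d[1], d[2])
      areas <- c(areas, area)
    }
  }
  mask_volume(acc, vol, "airway")
}

#' Bright-structure (vessel) exclusion mask
#'
#' Lung voxels above `vessel_threshold_hu` (-500 HU), morphologically
#' opened so that only structures at least `vessel_min_width_vox` voxels
#' across remain.
#'
#' @param vol a [ct_volume].
#' @param lung lung [mask_volume].
#' @param config configuration list.
#' @return a [mask_volume] with label `"vessel"`.
#' @export
exclude_bright_structures <- function(vol, lung, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  assert_same_grid(vol, lung, "volume and lung mask")
  bright <- lung$voxels & vol$voxels > config$vessel_threshold_hu
  w <- max(1L, as.integer(config$vessel_min_width_vox))
  if (w %% 2L == 0L) w <- w + 1L  # symmetric structuring element
  kern <- matrix(1, w, w)
  opened <- .slice_apply(bright, function(sl) EBImage::opening(sl, kern) > 0)
  mask_volume(opened & bright, vol, "vessel")
}
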