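# Synthetic chest phantom with ground-truth masks.
#
# The phantom reproduces the variability modes that make fixed-threshold
# cyst scoring fail on real longitudinal HRCT data: miscalibrated external
# air background, superior-inferior drift of airway radiodensity, patient-
# to-patient parenchymal density differences, and regional density
# elevation mimicking positional atelectasis.  Cyst spheres are rendered
# with partial volume (occupancy-weighted mixing against the local
# parenchyma) because the thin mixed shell around small cysts is precisely
# what global thresholds truncate on real scans.

#' Phantom specification
#'
#' @param shape voxel grid `(rows, columns, slices)`.
#' @param spacing voxel spacing mm `(row, column, slice)`.
#' @param background_hu external-air level (HU), within `[-1030, -950]`.
#' @param parenchyma_hu baseline non-cystic parenchyma level (HU), within
#'   `[-950, -700]` and at least 60 HU above `background_hu`.
#' @param parenchyma_gradient anterior-posterior additive ramp span (HU).
#' @param airway_drift length-2: airway HU at the most superior and most
#'   inferior extent; a linear profile in between.  `NULL` gives
#'   `background_hu + c(28, 8)` (apical elevation).
#' @param cyst_list data frame with columns `x, y, z` (mm, patient-style
#'   coordinates: x left-right from midline, y anterior-posterior from
#'   midline, z mm from the most superior slice) and `r` (radius mm).
#'   `NULL` gives a fixed default set of 12 cysts (6 per lung, radii
#'   6-9 mm, about 5 percent of lung volume).
#' @param vessel_list optional data frame of tube segments
#'   (`x1,y1,z1,x2,y2,z2,r`); `NULL` gives two small vessels per lung,
#'   `NA` gives none.
#' @param noise_sd additive Gaussian noise (HU).
#' @param seed integer RNG seed; the phantom is reproducible bit-for-bit.
#' @param kernel reconstruction-kernel tag carried by the volume.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 80L), spacing = c(1, 1, 2),
                         background_hu = -994, parenchyma_hu = -880,
                         parenchyma_gradient = 0, airway_drift = NULL,
                         cyst_list = NULL, vessel_list = NULL,
                         noise_sd = 10, seed = 1L, kernel = "SYNTHETIC") {
  if (background_hu < -1030 || background_hu > -950)
    stop("background_hu must lie in [-1030, -950]")
  if (parenchyma_hu < -950 || parenchyma_hu > -700)
    stop("parenchyma_hu must lie in [-950, -700]")
  if (parenchyma_hu - background_hu < 60)
    stop("parenchyma_hu must exceed background_hu by at least 60 HU; ",
         "below that contrast cysts are radiologically undefined")
  if (is.null(airway_drift)) airway_drift <- background_hu + c(28, 8)
  if (length(airway_drift) != 2) stop("airway_drift must have length 2")
  spec <- structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         background_hu = background_hu, parenchyma_hu = parenchyma_hu,
         parenchyma_gradient = parenchyma_gradient,
         airway_drift = as.numeric(airway_drift),
         cyst_list = cyst_list, vessel_list = vessel_list,
         noise_sd = noise_sd, seed = as.integer(seed), kernel = kernel),
    class = "phantom_spec")
  geom <- phantom_geometry(spec)
  if (is.null(spec$cyst_list)) spec$cyst_list <- default_cyst_list(geom)
  if (is.null(spec$vessel_list)) spec$vessel_list <- default_vessel_list(geom)
  if (length(spec$vessel_list) == 1 && is.na(spec$vessel_list))
    spec$vessel_list <- NULL
  if (any(spec$cyst_list$r < min(spacing)))
    stop("cyst radius must be at least one voxel")
  spec
}

#' Deterministic anatomy layout of a phantom
#'
#' Body and lung ellipsoids, trachea and main-bronchus capsules; all scaled
#' to the physical extent of the grid.  Exported so that tests and region
#' analyses can reconstruct truth geometry.
#'
#' @param spec a [phantom_spec].
#' @return list of geometric primitives (mm).
#' @export
phantom_geometry <- function(spec) {
  Lx <- spec$shape[2] * spec$spacing[2]
  Ly <- spec$shape[1] * spec$spacing[1]
  Lz <- spec$shape[3] * spec$spacing[3]
  sc <- Lx / 128
  carina <- c(0, -0.045 * Ly, 0.44 * Lz)
  hila <- list(right = c(0.155 * Lx, 0, 0.60 * Lz),
               left  = c(-0.155 * Lx, 0, 0.60 * Lz))
  list(
    Lx = Lx, Ly = Ly, Lz = Lz, scale = sc,
    body_semi = c(0.45 * Lx, 0.35 * Ly),
    body_hu = 40,
    lung_centers = list(right = c(0.22 * Lx, 0, 0.55 * Lz),
                        left  = c(-0.22 * Lx, 0, 0.55 * Lz)),
    lung_semi = c(0.17 * Lx, 0.25 * Ly, 0.39 * Lz),
    # airway calibres scale with the grid but stay physiological
    trachea = list(center = c(0, -0.045 * Ly), radius = min(7 * sc, 11),
                   z0 = 0, z1 = carina[3]),
    bronchi = list(right = rbind(carina, hila$right),
                   left  = rbind(carina, hila$left)),
    bronchus_radius = min(5 * sc, 7.5),
    wall_mm = 1.5,
    wall_hu = -50,
    vessel_hu = 30)
}

default_cyst_list <- function(geom) {
  u <- rbind(  # fractions of the lung semi-axes, radius in mm (128-mm scale)
    c( 0.30, -0.30, -0.40, 8),
    c(-0.25,  0.35, -0.25, 8),
    c( 0.20,  0.50,  0.10, 9),
    c(-0.35, -0.45,  0.27, 7),
    c( 0.33,  0.00,  0.50, 7),
    c(-0.10, -0.12, -0.75, 6))
  out <- do.call(rbind, lapply(c(1, -1), function(s) {
    ctr <- if (s > 0) geom$lung_centers$right else geom$lung_centers$left
    data.frame(x = ctr[1] + s * u[, 1] * geom$lung_semi[1],
               y = ctr[2] + u[, 2] * geom$lung_semi[2],
               z = ctr[3] + u[, 3] * geom$lung_semi[3],
               r = u[, 4] * geom$scale)
  }))
  rownames(out) <- NULL
  out
}

default_vessel_list <- function(geom) {
  seg <- function(ctr, s) {
    h <- c(0.16 * geom$Lx * s, 0.015 * geom$Ly, 0.58 * geom$Lz)
    rbind(
      c(h, h + c(s * 0.11 * geom$Lx, 0.15 * geom$Ly, 0.17 * geom$Lz), 2 * geom$scale),
      c(h, h + c(s * 0.09 * geom$Lx, -0.12 * geom$Ly, -0.11 * geom$Lz), 1.8 * geom$scale))
  }
  m <- rbind(seg(geom$lung_centers$right, 1), seg(geom$lung_centers$left, -1))
  out <- as.data.frame(m)
  names(out) <- c("x1", "y1", "z1", "x2", "y2", "z2", "r")
  out
}

# in-plane coordinate matrices (mm) and per-slice z positions
.phantom_coords <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]; nz <- spec$shape[3]
  y <- (seq_len(nr) - (nr + 1) / 2) * spec$spacing[1]  # anterior -> posterior
  x <- (seq_len(nc) - (nc + 1) / 2) * spec$spacing[2]  # left -> right
  list(X = matrix(x, nr, nc, byrow = TRUE), Y = matrix(y, nr, nc),
       zs = (seq_len(nz) - 1) * spec$spacing[3])
}

.ellipsoid_mask <- function(co, center, semi, shape) {
  Q <- ((co$X - center[1]) / semi[1])^2 + ((co$Y - center[2]) / semi[2])^2
  out <- array(FALSE, shape)
  for (k in seq_along(co$zs)) {
    rem <- 1 - ((co$zs[k] - center[3]) / semi[3])^2
    if (rem > 0) out[, , k] <- Q <= rem
  }
  out
}

# distance field (mm) from every voxel to a 3-D segment p1-p2
.segment_dist <- function(co, p1, p2, shape) {
  d <- p2 - p1
  L2 <- sum(d^2)
  out <- array(Inf, shape)
  for (k in seq_along(co$zs)) {
    z <- co$zs[k]
    t <- if (L2 == 0) 0 else
      ((co$X - p1[1]) * d[1] + (co$Y - p1[2]) * d[2] + (z - p1[3]) * d[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    out[, , k] <- sqrt((co$X - p1[1] - t * d[1])^2 +
                       (co$Y - p1[2] - t * d[2])^2 +
                       (z - p1[3] - t * d[3])^2)
  }
  out
}

.airway_profile_fun <- function(spec) {
  Lz <- spec$shape[3] * spec$spacing[3]
  function(z) spec$airway_drift[1] +
    (spec$airway_drift[2] - spec$airway_drift[1]) * z / Lz
}

.make_phantom_core <- function(spec, elevation_hu = 0, fraction = 0.4,
                               leak_radius = NULL) {
  geom <- phantom_geometry(spec)
  co <- .phantom_coords(spec)
  shape <- spec$shape
  nz <- shape[3]
  vox <- array(spec$background_hu, shape)

  # soft-tissue body: elliptical cylinder
  bodyQ <- (co$X / geom$body_semi[1])^2 + (co$Y / geom$body_semi[2])^2 <= 1
  body <- array(bodyQ, shape)
  vox[body] <- geom$body_hu

  # lungs
  lungs <- .ellipsoid_mask(co, geom$lung_centers$right, geom$lung_semi, shape) |
    .ellipsoid_mask(co, geom$lung_centers$left, geom$lung_semi, shape)
  par_val <- array(spec$parenchyma_hu, shape)
  if (spec$parenchyma_gradient != 0) {
    yr <- range(co$Y[1, 1], co$Y[nrow(co$Y), 1])
    ramp <- (co$Y - mean(co$Y)) / diff(range(co$Y)) * spec$parenchyma_gradient
    for (k in seq_len(nz)) par_val[, , k] <- par_val[, , k] + ramp
  }
  if (elevation_hu > 0) {
    # anterior `fraction` of lung depth raised by elevation_hu, with a
    # smooth 4-mm transition band at the boundary
    ylung <- geom$lung_centers$right[2] + c(-1, 1) * geom$lung_semi[2]
    y_b <- ylung[1] + fraction * diff(ylung)
    w <- pmin(pmax((y_b - co$Y) / 4 + 0.5, 0), 1)
    for (k in seq_len(nz)) par_val[, , k] <- par_val[, , k] + elevation_hu * w
  }
  vox[lungs] <- par_val[lungs]

  # airways: vertical trachea + two main bronchi, sealed by soft walls
  tr <- geom$trachea
  trd2 <- (co$X - tr$center[1])^2 + (co$Y - tr$center[2])^2
  dist_tr <- array(Inf, shape)
  ktr <- which(co$zs >= tr$z0 & co$zs <= tr$z1)
  for (k in ktr) dist_tr[, , k] <- sqrt(trd2)
  dist_br <- pmin(
    .segment_dist(co, geom$bronchi$right[1, ], geom$bronchi$right[2, ], shape),
    .segment_dist(co, geom$bronchi$left[1, ], geom$bronchi$left[2, ], shape))
  interior <- (dist_tr <= tr$radius) | (dist_br <= geom$bronchus_radius)
  wall <- ((dist_tr <= tr$radius + geom$wall_mm) |
             (dist_br <= geom$bronchus_radius + geom$wall_mm)) & !interior

  cysts <- spec$cyst_list
  if (!is.null(leak_radius)) {
    # a giant cyst sitting on the end of the right bronchus, with the wall
    # carved away at the junction so the airway opens directly into it
    b <- geom$bronchi$right
    dir <- (b[2, ] - b[1, ]) / sqrt(sum((b[2, ] - b[1, ])^2))
    ctr <- b[2, ] + dir * (leak_radius - 1)
    cysts <- rbind(cysts, data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                                     r = leak_radius))
    leak_d <- .segment_dist(co, ctr, ctr, shape)
    wall <- wall & !(leak_d <= leak_radius + geom$wall_mm)
  }
  vox[wall] <- geom$wall_hu
  prof <- .airway_profile_fun(spec)
  for (k in seq_len(nz)) {
    sl <- vox[, , k]
    sl[interior[, , k]] <- prof(co$zs[k])
    vox[, , k] <- sl
  }

  # vessels
  truth_vessel <- array(FALSE, shape)
  if (!is.null(spec$vessel_list)) {
    for (i in seq_len(nrow(spec$vessel_list))) {
      v <- spec$vessel_list[i, ]
      dv <- .segment_dist(co, c(v$x1, v$y1, v$z1), c(v$x2, v$y2, v$z2), shape)
      m <- dv <= v$r & lungs & !interior & !wall
      vox[m] <- geom$vessel_hu
      truth_vessel <- truth_vessel | m
    }
  }

  # cysts: partial-volume rendered air spheres tracking the airway profile
  w_edge <- mean(spec$spacing)
  truth_cyst <- array(FALSE, shape)
  for (i in seq_len(nrow(cysts))) {
    cy <- cysts[i, ]
    dcy <- .segment_dist(co, c(cy$x, cy$y, cy$z), c(cy$x, cy$y, cy$z), shape)
    occ <- pmin(pmax(0.5 + (cy$r - dcy) / w_edge, 0), 1)
    touched <- occ > 0 & !interior & !wall
    if (is.null(leak_radius) || i <= nrow(spec$cyst_list)) {
      core <- dcy <= cy$r
      if (any(core & !lungs)) stop("cyst ", i, " is not strictly inside a lung")
      if (any(core & (interior | wall))) stop("cyst ", i, " overlaps the airway")
    }
    for (k in seq_len(nz)) {
      ok <- touched[, , k]
      if (!any(ok)) next
      sl <- vox[, , k]
      sl[ok] <- occ[, , k][ok] * prof(co$zs[k]) + (1 - occ[, , k][ok]) * sl[ok]
      vox[, , k] <- sl
    }
    truth_cyst <- truth_cyst | (dcy <= cy$r & !interior & !wall)
  }
  truth_vessel <- truth_vessel & !truth_cyst

  if (spec$noise_sd > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(spec$seed)
    vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd), shape)
  }

  vol <- ct_volume(vox, spec$spacing, kernel = spec$kernel)
  truth_lung <- lungs & !interior & !wall
  list(volume = vol,
       truth_lung = mask_volume(truth_lung, vol, "truth_lung"),
       truth_airway = mask_volume(interior, vol, "truth_airway"),
       truth_cyst = mask_volume(truth_cyst, vol, "truth_cyst"),
       truth_vessel = mask_volume(truth_vessel, vol, "truth_vessel"),
       spec = spec)
}

#' Generate a synthetic chest phantom
#'
#' Builds a soft-tissue body in external air, two parenchyma-filled lung
#' ellipsoids, a trachea splitting into two sealed main bronchi carrying a
#' linear superior-inferior radiodensity drift, optional vessels, and
#' partial-volume cyst spheres whose air value tracks the airway profile at
#' their slice.  Additive Gaussian noise is seeded and reproducible.
#'
#' @param spec a [phantom_spec].
#' @return list (`phantom_bundle`) with `volume` ([ct_volume]), truth masks
#'   `truth_lung`, `truth_airway`, `truth_cyst`, `truth_vessel`
#'   ([mask_volume]), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) .make_phantom_core(spec)

#' Phantom with positional-atelectasis-like anterior density elevation
#'
#' As [make_phantom()], but the anterior `fraction` of the lung depth is
#' raised by `elevation_hu` (smooth 4-mm transition band).  Cyst air values
#' and truth masks are unchanged: cysts are air-filled, only the parenchyma
#' around them is elevated.
#'
#' @param spec a [phantom_spec].
#' @param elevation_hu density elevation amplitude (HU, `>= 0`).
#' @param fraction anterior fraction of lung depth affected, in (0, 1).
#' @export
make_atelectasis_phantom <- function(spec = phantom_spec(), elevation_hu = 100,
                                     fraction = 0.4) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (elevation_hu < 0) stop("elevation_hu must be >= 0")
  .make_phantom_core(spec, elevation_hu = elevation_hu, fraction = fraction)
}

#' Phantom in which a main bronchus opens into a giant cyst
#'
#' Constructed failure case for airway region growing: the sealing wall at
#' the end of the right main bronchus is carved away and a large cyst placed
#' directly against the opening, so that naive region growing floods the
#' cyst unless leak control stops it.
#'
#' @param spec a [phantom_spec].
#' @param radius_mm radius of the giant cyst.
#' @export
make_airway_leak_phantom <- function(spec = phantom_spec(), radius_mm = 18) {
  .make_phantom_core(spec, leak_radius = radius_mm)
}

#' Random phantom specification
#'
#' Draws a phantom spanning the documented variability ranges: external-air
#' background uniform in `[-1018, -954]` HU, parenchyma uniform in
#' `[max(-950, background + 80), -750]` HU (the 80-HU floor keeps the
#' air-parenchyma contrast physiological), apical airway elevation 10-25 HU
#' fading to 0-10 HU inferiorly, a mild anterior-posterior gradient, and
#' 8-14 random non-overlapping cysts of radius 4-10 mm.
#'
#' @param seed integer seed controlling every draw.
#' @param shape,spacing grid geometry.
#' @param noise_sd noise level (HU).
#' @export
random_phantom_spec <- function(seed, shape = c(128L, 128L, 80L),
                                spacing = c(1, 1, 2), noise_sd = 10) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  bg <- stats::runif(1, -1018, -954)
  par <- stats::runif(1, max(-950, bg + 80), -750)
  drift <- bg + c(stats::runif(1, 10, 25), stats::runif(1, 0, 10))
  grad <- stats::runif(1, 0, 30)
  base <- phantom_spec(shape = shape, spacing = spacing, background_hu = bg,
                       parenchyma_hu = par, parenchyma_gradient = grad,
                       airway_drift = drift, cyst_list = NULL,
                       noise_sd = noise_sd, seed = seed)
  geom <- phantom_geometry(base)
  ncy <- sample(8:14, 1)
  placed <- data.frame()
  tries <- 0
  while (nrow(placed) < ncy && tries < 500) {
    tries <- tries + 1
    r <- stats::runif(1, 4, 10) * geom$scale
    side <- sample(c("right", "left"), 1)
    ctr <- geom$lung_centers[[side]]
    u <- stats::runif(3, -0.85, 0.85)
    shrunk <- geom$lung_semi - (r + 2)
    if (any(shrunk <= 0)) next
    if (sum((u * geom$lung_semi / shrunk)^2) > 0.9) next
    p <- ctr + u * geom$lung_semi
    # keep clear of the airway tree and of other cysts
    air_d <- min(
      .point_seg_dist(p, c(geom$trachea$center, geom$trachea$z0),
                      c(geom$trachea$center, geom$trachea$z1)),
      .point_seg_dist(p, geom$bronchi$right[1, ], geom$bronchi$right[2, ]),
      .point_seg_dist(p, geom$bronchi$left[1, ], geom$bronchi$left[2, ]))
    if (air_d < r + geom$bronchus_radius + geom$wall_mm + 2) next
    if (nrow(placed) > 0) {
      dd <- sqrt((placed$x - p[1])^2 + (placed$y - p[2])^2 + (placed$z - p[3])^2)
      if (any(dd < placed$r + r + 1)) next
    }
    placed <- rbind(placed, data.frame(x = p[1], y = p[2], z = p[3], r = r))
  }
  base$cyst_list <- placed
  base
}

.point_seg_dist <- function(p, a, b) {
  d <- b - a
  L2 <- sum(d^2)
  t <- if (L2 == 0) 0 else min(max(sum((p - a) * d) / L2, 0), 1)
  sqrt(sum((p - a - t * d)^2))
}

#' Simulate a longitudinal cyst-score series
#'
#' Linear trend plus Gaussian jitter, exams every `interval_years` years;
#' the fixture for the longitudinal-inconsistency metric.
#'
#' @param n_exams number of examinations (`>= 3`).
#' @param trend cyst-score change per year.
#' @param jitter_sd exam-to-exam score jitter (cyst-score units).
#' @param seed RNG seed.
#' @param baseline score at the first exam.
#' @param interval_years spacing between exams.
#' @param patient_id identifier carried by the series.
#' @return a [score_series].
#' @export
make_score_series <- function(n_exams, trend = 0.01, jitter_sd = 0.01,
                              seed = 1L, baseline = 0.15, interval_years = 2,
                              patient_id = "SIM") {
  if (n_exams < 3) stop("n_exams must be >= 3")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  times <- (seq_len(n_exams) - 1) * interval_years
  scores <- baseline + trend * times +
    if (jitter_sd > 0) stats::rnorm(n_exams, 0, jitter_sd) else 0
  score_series(patient_id, times, scores)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
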