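# Shared fixtures, built once per test run.  Phantoms are deterministic in
# their seed, so caching them is safe.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a cyst that fits the 64 x 64 x 24 grid used by fast unit tests
tiny_cysts <- data.frame(x = 17, y = -5, z = 32, r = 4)

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(64L, 64L, 24L), spacing = c(1, 1, 2),
         cyst_list = tiny_cysts),
    list(...))
  do.call(phantom_spec, args)
}

default_bundle <- function()
  fixture("default_bundle", function() make_phantom(phantom_spec()))

default_run <- function()
  fixture("default_run", function() segment_volume(default_bundle()$volume))

small_bundle <- function()
  fixture("small_bundle", function()
    make_phantom(phantom_spec(shape = c(96L, 96L, 40L),
                              parenchyma_gradient = 20)))

small_run <- function()
  fixture("small_run", function() segment_volume(small_bundle()$volume))

# atelectasis study conditions: elevation 100 HU over the anterior 40%,
# noise sd 20 HU
atelectasis_bundle <- function()
  fixture("atelectasis_bundle", function()
    make_atelectasis_phantom(phantom_spec(noise_sd = 20),
                             elevation_hu = 100, fraction = 0.4))

atelectasis_run <- function()
  fixture("atelectasis_run", function()
    segment_volume(atelectasis_bundle()$volume))

# anterior/posterior region arrays for a bundle, excluding a +-3 mm band
# around the elevation boundary
ap_regions <- function(spec, fraction = 0.4, band_mm = 3) {
  geom <- phantom_geometry(spec)
  ylung <- geom$lung_centers$right[2] + c(-1, 1) * geom$lung_semi[2]
  y_b <- ylung[1] + fraction * diff(ylung)
  nr <- spec$shape[1]
  yv <- (seq_len(nr) - (nr + 1) / 2) * spec$spacing[1]
  rep_plane <- function(v) array(rep(v, times = prod(spec$shape[2:3])),
                                 spec$shape)
  list(anterior = rep_plane(yv < y_b - band_mm),
       posterior = rep_plane(yv > y_b + band_mm))
}

# independent brute-force weighted smoothed-histogram mode (R oracle)
oracle_local_mode <- function(img, include, center, spacing, lo, hi,
                              diameter_mm, sigma_mm, smooth_sd, min_frac) {
  rad <- diameter_mm / 2
  nb <- ceiling(hi - lo)
  if (nb < 1) return(NA_real_)
  hist <- numeric(nb)
  total_w <- 0
  wsum <- 0
  hr <- floor(rad / spacing[1]); hc <- floor(rad / spacing[2])
  for (dr in -hr:hr) for (dc in -hc:hc) {
    dmm2 <- (dr * spacing[1])^2 + (dc * spacing[2])^2
    if (dmm2 > rad^2) next
    w <- exp(-0.5 * dmm2 / sigma_mm^2)
    total_w <- total_w + w
    r <- center[1] + dr; c <- center[2] + dc
    if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) next
    if (!include[r, c]) next
    v <- img[r, c]
    if (v < lo || v > hi) next
    b <- min(floor(v - lo), nb - 1)
    hist[b + 1] <- hist[b + 1] + w
    wsum <- wsum + w
  }
  if (wsum < min_frac * total_w) return(NA_real_)
  sm <- sapply(seq_len(nb), function(j)
    sum(hist * exp(-0.5 * ((seq_len(nb) - j) / smooth_sd)^2)))
  lo + (which.max(sm) - 1) + 0.5
}
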