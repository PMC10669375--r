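test_that("local mode agrees with a brute-force weighted-histogram oracle", {
  set.seed(21)
  cfg <- default_config()
  cfg$window_diameter_mm <- 9
  cfg$window_sigma_mm <- 2.5
  for (rep in 1:12) {
    # two well-separated clusters with random mixing weight
    n <- 24 * 24
    frac <- stats::runif(1, 0.25, 0.75)
    vals <- ifelse(stats::runif(n) < frac,
                   stats::rnorm(n, -860, 4), stats::rnorm(n, -720, 4))
    img <- array(vals, c(24, 24, 1))
    include <- array(stats::runif(n) > 0.2, c(24, 24, 1))
    vol <- ct_volume(img, c(1, 1, 1))
    center <- c(sample(8:16, 1), sample(8:16, 1), 1)
    got <- local_mode(vol, center, range = c(-950, -500),
                      exclusion = !include, config = cfg)
    want <- oracle_local_mode(img[, , 1], include[, , 1], center[1:2],
                              c(1, 1), -950, -500, 9, 2.5,
                              cfg$hist_smooth_sd_hu,
                              cfg$availability_min_weight_frac)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("single-value, bimodal and range-exclusion cases behave as stated", {
  mkvol <- function(fill) ct_volume(array(fill, c(31, 31, 1)), c(1, 1, 1))
  cfg <- default_config()
  # uniform neighborhood: mode at the value (1-HU bin centre)
  expect_lt(abs(local_mode(mkvol(-850), c(16, 16, 1), c(-965, -500),
                           config = cfg) - (-850)), 0.51)
  # 60/40 weight split: the heavier value wins
  v <- array(-700, c(31, 31, 1))
  v[, 1:19, 1] <- -850  # ~60% of columns, uniform window weighting aside
  cfg2 <- cfg; cfg2$window_sigma_mm <- 1e6  # ~flat profile
  expect_lt(abs(local_mode(ct_volume(v, c(1, 1, 1)), c(16, 16, 1),
                           c(-965, -500), config = cfg2) - (-850)), 0.51)
  # scattered vessel-like pixels above -500 are outside the range
  set.seed(3)
  v2 <- array(-850, c(31, 31, 1))
  v2[sample(31 * 31, 120)] <- -300
  expect_lt(abs(local_mode(ct_volume(v2, c(1, 1, 1)), c(16, 16, 1),
                           c(-965, -500), config = cfg) - (-850)), 0.51)
})

test_that("the parenchyma map recovers a flat density field", {
  sp <- phantom_spec(shape = c(96L, 96L, 40L), parenchyma_hu = -918,
                     background_hu = -1006)
  b <- make_phantom(sp)
  res <- segment_volume(b$volume)
  pm <- res$pmap
  lung_av <- pm$available & b$truth_lung$voxels
  frac_close <- mean(abs(pm$values[lung_av] - (-918)) <= 5)
  expect_gte(frac_close, 0.95)
  expect_false(any(pm$available & !res$lung$voxels))
})

test_that("the map tracks regional elevation (atelectasis)", {
  b <- atelectasis_bundle()
  res <- atelectasis_run()
  reg <- ap_regions(b$spec, 0.4)
  pm <- res$pmap
  ant <- pm$available & reg$anterior
  post <- pm$available & reg$posterior
  dmed <- stats::median(pm$values[ant]) - stats::median(pm$values[post])
  expect_lt(abs(dmed - 100), 10)
})

test_that("centres of cysts larger than the window are unavailable", {
  # a 50-mm cyst (window is 35 mm) inside an enlarged lung
  ctr <- c(75, 20, 130)
  sp <- phantom_spec(shape = c(160L, 160L, 80L), spacing = c(1.75, 1.75, 2.5),
                     cyst_list = data.frame(x = ctr[1], y = ctr[2],
                                            z = ctr[3], r = 25),
                     vessel_list = NA)
  b <- make_phantom(sp)
  res <- segment_volume(b$volume)
  # voxel indices within 3 mm (in plane) / 2 slices of the cyst centre
  nr <- sp$shape[1]; nc <- sp$shape[2]
  row0 <- ctr[2] / sp$spacing[1] + (nr + 1) / 2
  col0 <- ctr[1] / sp$spacing[2] + (nc + 1) / 2
  k0 <- ctr[3] / sp$spacing[3] + 1
  rows <- round(row0 + (-2:2)); cols <- round(col0 + (-2:2))
  ks <- round(k0 + (-2:2))
  av <- res$pmap$available[rows, cols, ks]
  expect_true(mean(av) < 0.05)
  # the fallback branch still classifies those voxels as cystic
  cys <- res$cyst$voxels[rows, cols, ks]
  expect_gte(mean(cys), 0.9)
})

test_that("a global HU offset shifts available I_p values by exactly that", {
  b <- make_phantom(tiny_spec(noise_sd = 8))
  res <- segment_volume(b$volume)
  c0 <- 23
  v2 <- ct_volume(b$volume$voxels + c0, b$volume$spacing)
  lung2 <- mask_volume(res$lung$voxels, v2, "lung")
  aw2 <- mask_volume(res$airway$voxels, v2, "airway")
  vs2 <- mask_volume(res$vessel$voxels, v2, "vessel")
  ref2 <- build_air_reference(res$ref$I_background + c0,
                              list(profile = res$ref$I_airway + c0,
                                   valid = res$ref$valid))
  pm2 <- parenchyma_density_map(v2, lung2, aw2, vs2, ref2)
  expect_identical(pm2$available, res$pmap$available)
  av <- pm2$available
  expect_lt(max(abs(pm2$values[av] - res$pmap$values[av] - c0)), 1e-9)
})
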