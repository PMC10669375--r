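test_that("identical spec and seed give bit-identical phantoms", {
  a <- make_phantom(tiny_spec(seed = 42))
  b <- make_phantom(tiny_spec(seed = 42))
  expect_identical(a$volume$voxels, b$volume$voxels)
  c <- make_phantom(tiny_spec(seed = 43))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("truth-mask containment and disjointness hold for random specs", {
  for (s in 1:100) {
    sp <- random_phantom_spec(5000 + s, shape = c(64L, 64L, 24L))
    b <- make_phantom(sp)
    expect_true(all(b$truth_cyst$voxels <= b$truth_lung$voxels),
                info = paste("cyst within lung, seed", s))
    expect_identical(sum(b$truth_cyst$voxels & b$truth_airway$voxels), 0L,
                     info = paste("cyst/airway disjoint, seed", s))
    expect_identical(sum(b$truth_lung$voxels & b$truth_airway$voxels), 0L,
                     info = paste("lung/airway disjoint, seed", s))
  }
})

test_that("per-region voxel statistics match the spec", {
  sp <- tiny_spec(noise_sd = 8, background_hu = -1006)
  b <- make_phantom(sp)
  geom <- phantom_geometry(sp)
  co <- lamcyst:::.phantom_coords(sp)
  outside <- array((co$X / geom$body_semi[1])^2 +
                     (co$Y / geom$body_semi[2])^2 > 1.1, sp$shape)
  n <- sum(outside)
  expect_lt(abs(mean(b$volume$voxels[outside]) - (-1006)),
            3 * sp$noise_sd / sqrt(n))
  # parenchyma mean away from structures
  par <- b$truth_lung$voxels & !b$truth_vessel$voxels
  core <- par
  for (k in seq_len(dim(core)[3]))
    core[, , k] <- EBImage::erode(core[, , k], EBImage::makeBrush(9, "disc")) > 0
  core <- core & !b$truth_cyst$voxels
  expect_lt(abs(mean(b$volume$voxels[core]) - sp$parenchyma_hu),
            3 * sp$noise_sd / sqrt(sum(core)) + 0.5)
})

test_that("cyst interiors track the airway drift profile at their slice", {
  sp <- tiny_spec(noise_sd = 0, airway_drift = c(-1000, -960))
  b <- make_phantom(sp)
  prof <- lamcyst:::.airway_profile_fun(sp)
  zs <- lamcyst:::.phantom_coords(sp)$zs
  cy <- sp$cyst_list[1, ]
  for (k in which(abs(zs - cy$z) <= cy$r - 3)) {
    interior <- b$truth_cyst$voxels[, , k]
    co <- lamcyst:::.phantom_coords(sp)
    d2 <- (co$X - cy$x)^2 + (co$Y - cy$y)^2
    interior <- interior & d2 <= max((cy$r - 2)^2 - (zs[k] - cy$z)^2, 0)
    if (!any(interior)) next
    expect_equal(mean(b$volume$voxels[, , k][interior]), prof(zs[k]),
                 tolerance = 1e-9)
  }
})

test_that("atelectasis phantom elevates the anterior region by the given amount", {
  sp <- phantom_spec(noise_sd = 20)
  b0 <- make_phantom(sp)
  bsame <- make_atelectasis_phantom(sp, elevation_hu = 0)
  expect_identical(b0$volume$voxels, bsame$volume$voxels)

  b <- make_atelectasis_phantom(sp, elevation_hu = 100, fraction = 0.4)
  reg <- ap_regions(sp, 0.4)
  par <- b$truth_lung$voxels & !b$truth_cyst$voxels & !b$truth_vessel$voxels
  ant <- par & reg$anterior; post <- par & reg$posterior
  expect_gte(sum(ant), 1e4); expect_gte(sum(post), 1e4)
  dmean <- mean(b$volume$voxels[ant]) - mean(b$volume$voxels[post])
  expect_lt(abs(dmean - 100), 5)
  expect_identical(b$truth_cyst$voxels, b0$truth_cyst$voxels)

  # cysts are air-filled: their interiors are not elevated
  sp0 <- phantom_spec(noise_sd = 0)
  c0 <- make_phantom(sp0)
  c1 <- make_atelectasis_phantom(sp0, elevation_hu = 100, fraction = 0.4)
  interior <- c0$truth_cyst$voxels
  for (k in seq_len(dim(interior)[3]))
    interior[, , k] <- EBImage::erode(interior[, , k],
                                      EBImage::makeBrush(5, "disc")) > 0
  expect_equal(c0$volume$voxels[interior], c1$volume$voxels[interior],
               tolerance = 1e-9)
})

test_that("simulated score series have the requested shape and jitter", {
  s <- make_score_series(9, trend = 0.01, jitter_sd = 0, seed = 1)
  expect_length(s$scores, 9)
  expect_true(all(abs(series_inconsistencies(s)) < 1e-12))

  # mean triple inconsistency matches the closed form sd * sqrt(2/pi)
  vals <- unlist(lapply(1:1500, function(i)
    series_inconsistencies(make_score_series(9, trend = 0.005,
                                             jitter_sd = 0.015, seed = i))))
  expect_gte(length(vals), 1e4)
  expect_lt(abs(mean(vals) / (0.015 * sqrt(2 / pi)) - 1), 0.10)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(background_hu = -900), "background_hu")
  expect_error(phantom_spec(parenchyma_hu = -960), "parenchyma_hu")
  expect_error(phantom_spec(background_hu = -954, parenchyma_hu = -940),
               "contrast")
  expect_error(
    make_phantom(tiny_spec(cyst_list = data.frame(x = 0, y = 0, z = 40, r = 4))),
    "inside a lung|overlaps the airway")
  expect_error(make_atelectasis_phantom(phantom_spec(), fraction = 1.2),
               "fraction")
})
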