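test_that("collinear and constant triples have zero inconsistency", {
  expect_equal(triple_inconsistency(c(0, 1, 2), c(0.10, 0.20, 0.30)), 0,
               tolerance = 1e-12)
  expect_equal(triple_inconsistency(c(0, 3, 7), c(0.2, 0.2, 0.2)), 0,
               tolerance = 1e-12)
  expect_error(triple_inconsistency(c(0, 0, 1), c(0.1, 0.2, 0.3)),
               "duplicate")
})

test_that("triple inconsistency equals sqrt(SSR) from a least-squares oracle", {
  # worked example
  got <- triple_inconsistency(c(0, 1, 2), c(0.1, 0.3, 0.1))
  fit <- stats::lm(y ~ x, data.frame(x = c(0, 1, 2), y = c(0.1, 0.3, 0.1)))
  expect_equal(got, sqrt(sum(stats::residuals(fit)^2)), tolerance = 1e-12)

  set.seed(99)
  for (i in 1:1000) {
    t <- sort(stats::runif(3, 0, 20))
    while (anyDuplicated(t)) t <- sort(stats::runif(3, 0, 20))
    s <- stats::runif(3)
    want <- sqrt(sum(stats::residuals(stats::lm(s ~ t))^2))
    got <- triple_inconsistency(t, s)
    expect_lt(abs(got - want), 1e-10 * max(want, 1e-30))
  }
})

test_that("a series of n exams yields n - 2 inconsistency measures", {
  s9 <- make_score_series(9, jitter_sd = 0.01, seed = 4)
  expect_length(series_inconsistencies(s9), 7)
  s3 <- make_score_series(3, jitter_sd = 0.01, seed = 4)
  expect_length(series_inconsistencies(s3), 1)
  short <- score_series("p", c(0, 1), c(0.1, 0.2))
  expect_message(v <- series_inconsistencies(short), "fewer than 3")
  expect_length(v, 0)
  for (n in sample(3:50, 8))
    expect_length(series_inconsistencies(
      make_score_series(n, trend = 0.002, jitter_sd = 0.005, seed = n)),
      n - 2)
})

test_that("max inconsistency matches the brute-force maximum", {
  s <- make_score_series(12, jitter_sd = 0.02, seed = 7)
  expect_equal(max_inconsistency(s), max(series_inconsistencies(s)))
  expect_equal(max_inconsistency(score_series("p", 0, 0.2)), NA_real_)
  z <- make_score_series(6, jitter_sd = 0, seed = 1)
  expect_equal(max_inconsistency(z), 0, tolerance = 1e-12)
})

test_that("inconsistency is invariant to affine-in-time score shifts and scales linearly", {
  set.seed(5)
  for (i in 1:25) {
    t <- sort(stats::runif(3, 0, 10))
    s <- stats::runif(3, 0, 0.5)
    base <- triple_inconsistency(t, s)
    a <- stats::runif(1, -1, 1); b <- stats::runif(1, -0.1, 0.1)
    expect_equal(triple_inconsistency(t, s + a + b * t), base,
                 tolerance = 1e-9)
    cc <- stats::runif(1, 0.1, 3)
    expect_equal(triple_inconsistency(t, cc * s), cc * base,
                 tolerance = 1e-9)
  }
})

test_that("squared Pearson correlation handles exact, degenerate and constructed cases", {
  x <- 1:10
  expect_equal(pearson_r2(x, 2 * x + 1), 1.0, tolerance = 1e-12)
  expect_true(is.na(pearson_r2(x, rep(3, 10))))
  expect_error(pearson_r2(c(1, 2), c(3, 4)), "3 complete")
  # construct pairs whose sample correlation is exactly 0.9
  set.seed(8)
  e <- stats::rnorm(10)
  xs <- scale(x)[, 1]
  es <- stats::residuals(stats::lm(e ~ x))
  es <- es / sqrt(sum(es^2)) * sqrt(9)  # standardized, orthogonal to x
  y <- 0.9 * xs + sqrt(1 - 0.81) * es
  expect_lt(abs(pearson_r2(x, y) - 0.81), 1e-6)
  # missing pairs are dropped
  x2 <- c(x, NA); y2 <- c(2 * x + 1, 5)
  expect_equal(pearson_r2(x2, y2), 1.0, tolerance = 1e-12)
})

test_that("PFT correlation joins on patient and visit date", {
  scores <- data.frame(patient_id = rep("p1", 4),
                       exam_date = as.Date("2020-01-01") + c(0, 365, 730, 1095),
                       cyst_score = c(0.10, 0.15, 0.20, 0.25))
  pft <- data.frame(patient_id = "p1",
                    exam_date = as.Date("2020-01-01") + c(0, 365, 730, 1095),
                    FEV1_pp = c(90, 80, 70, 60),
                    DLco_adj_pp = c(80, NA, 60, 50))
  out <- correlate_pft(scores, pft)
  expect_equal(out$r2[out$measure == "FEV1_pp"], 1, tolerance = 1e-12)
  expect_equal(out$n[out$measure == "FEV1_pp"], 4L)
  expect_equal(out$n[out$measure == "DLco_adj_pp"], 3L)
  # a 2-day offset fails the default same-visit window but passes +-7 days
  pft2 <- pft
  pft2$exam_date <- pft2$exam_date + 2
  out0 <- correlate_pft(scores, pft2)
  expect_equal(out0$n[out0$measure == "FEV1_pp"], 0L)
  out7 <- correlate_pft(scores, pft2, window_days = 7)
  expect_equal(out7$n[out7$measure == "FEV1_pp"], 4L)
})

test_that("cohort summary aggregates per-patient measures and maxima", {
  sl <- lapply(1:5, function(i)
    make_score_series(6, jitter_sd = 0.01, seed = i, patient_id = paste0("p", i)))
  sm <- summarize_inconsistency(sl)
  expect_equal(nrow(sm$measures), 5 * 4)
  expect_length(sm$patient_max, 5)
  expect_true(all(sm$patient_max >= 0))
  expect_equal(sm$mean, mean(sm$measures$inconsistency))
})

test_that("score series constructor validates its invariants", {
  expect_error(score_series("p", c(0, 1, 1), c(0.1, 0.2, 0.3)), "increasing")
  expect_error(score_series("p", c(0, 1), c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(score_series("p", c(0, 1), 0.1), "length")
})
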