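test_that("ROI series extraction averages over the ROI per frame", {
  mv <- movie(lapply(1:5, function(i) matrix(i * 10, 20, 20)),
              time_step_s = 120)
  s <- extract_roi_series(mv, roi(3, 3, 5, 5))
  expect_equal(s$time_s, (0:4) * 120)
  expect_equal(s$intensity, (1:5) * 10)
  one <- extract_roi_series(movie(matrix(4, 8, 8)), roi(1, 1, 8, 8))
  expect_equal(nrow(one), 1)
})

test_that("bleach detection finds the dominant drop and rejects its absence", {
  cv <- tibble::tibble(time_s = (0:4) * 120,
                       intensity = c(100, 100, 10, 40, 70))
  expect_equal(detect_bleach(cv), 3)
  rising <- tibble::tibble(time_s = (0:4) * 120,
                           intensity = c(10, 20, 30, 40, 50))
  expect_error(detect_bleach(rising), "no qualifying bleach")
  shallow <- tibble::tibble(time_s = (0:4) * 120,
                            intensity = c(100, 100, 70, 80, 90))
  expect_error(detect_bleach(shallow), "no qualifying bleach")
  expect_error(detect_bleach(cv[1:2, ]), "at least 3")
})

test_that("recovery percent matches the closed form on noise-free curves", {
  g <- generate_frap_series(0.5, 180, noise_sigma = 0, seed = 1)
  expect_equal(recovery_percent(g$curve, 900), 100 * 0.5 * (1 - exp(-5)),
               tolerance = 0.5)
  # boundary values of the normalization
  b <- detect_bleach(g$curve)
  expect_equal(recovery_percent(g$curve, 0), 0, tolerance = 1e-9)
  full <- generate_frap_series(1, 120, noise_sigma = 0, duration_s = 2400,
                               seed = 1)
  expect_equal(recovery_percent(full$curve, 2000), 100, tolerance = 0.5)
  expect_error(recovery_percent(g$curve, 5000), "outside")
})

test_that("recovery percent is invariant under affine intensity rescaling", {
  g <- generate_frap_series(0.7, 200, noise_sigma = 0.02, seed = 3)
  v <- recovery_percent(g$curve, 600)
  scaled <- dplyr::mutate(g$curve, intensity = intensity * 3.7 + 40)
  expect_equal(recovery_percent(scaled, 600), v, tolerance = 1e-9)
})

test_that("recovery percent converges to 100 x mobile fraction", {
  for (mf in c(0.4, 0.8)) {
    g <- generate_frap_series(mf, 120, noise_sigma = 0, duration_s = 2400,
                              seed = 1)
    tail_t <- max(g$curve$time_s) - g$curve$time_s[detect_bleach(g$curve)]
    expect_equal(recovery_percent(g$curve, tail_t), 100 * mf,
                 tolerance = 0.2)
  }
})

test_that("exponential fit recovers noise-free parameters", {
  g <- generate_frap_series(0.9, 120, noise_sigma = 0, seed = 1)
  fit <- fit_recovery(g$curve)
  expect_equal(fit$mobile_fraction, 0.9, tolerance = 0.01)
  expect_equal(fit$tau_s, 120, tolerance = 0.05 * 120)
  expect_s3_class(fit, "frap_fit")
  expect_equal(glance(fit)$mobile_fraction, fit$mobile_fraction)
  expect_equal(nrow(tidy(fit)), 5)
  # flat post-bleach series: zero mobile fraction
  flat <- generate_frap_series(0, 180, noise_sigma = 0, seed = 1)
  expect_equal(fit_recovery(flat$curve)$mobile_fraction, 0)
})

test_that("mobile-fraction estimation is unbiased and precise under noise", {
  for (mf in c(0.5, 0.9)) {
    est <- vapply(1:50, function(i) {
      g <- generate_frap_series(mf, 180, noise_sigma = 0.02, seed = 1000 + i)
      fit_recovery(g$curve)$mobile_fraction
    }, numeric(1))
    expect_lt(abs(mean(est) - mf), 0.02)
    expect_lt(sd(est), 0.05)
  }
})

test_that("plateau detection compares the last two samples against F_pre", {
  g <- generate_frap_series(0.8, 120, noise_sigma = 0, duration_s = 1800,
                            seed = 1)  # sampled to > 5 tau
  expect_true(plateau_reached(g$curve, 0.02))
  rising <- generate_frap_series(0.9, 2000, noise_sigma = 0, seed = 1)
  expect_false(plateau_reached(rising$curve, 0.02))
  const <- tibble::tibble(time_s = (0:5) * 120,
                          intensity = c(100, 100, 10, 30, 50, 50))
  expect_true(plateau_reached(const, 0.02))
})
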