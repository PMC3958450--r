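fast_preset <- function(...) {
  # small variant of the fragmented-condition preset, for cheap tests
  p <- mito_preset("mutant_mito")
  p$n_objects <- 4
  p$field_px <- 160
  p[names(list(...))] <- list(...)
  mito_preset(p)
}

test_that("mito movie generation is bit-reproducible for a fixed seed", {
  a <- generate_mito_movie(fast_preset(), 4, seed = 5)
  b <- generate_mito_movie(fast_preset(), 4, seed = 5)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
  c <- generate_mito_movie(fast_preset(), 4, seed = 6)
  expect_false(identical(a$movie$frames, c$movie$frames))
})

test_that("true lengths follow the preset: range, oscillation amplitude, identity stability", {
  gm <- generate_mito_movie("control_mito", 8, seed = 1)
  per <- split(gm$truth, gm$truth$object)
  expect_length(per, 6)
  for (d in per) {
    expect_equal(nrow(d), 8)
    # (max - min)/mean of the true length series equals the preset amplitude
    expect_equal((max(d$true_length_um) - min(d$true_length_um)) /
                   mean(d$true_length_um), 1.0, tolerance = 1e-9)
    # length scales are exactly proportional to the recorded oscillation
    expect_equal(sd(d$true_length_um / d$scale), 0, tolerance = 1e-9)
  }
  # control condition: filaments 5-10 um (at scale 1)
  base_len <- vapply(per, function(d) mean(d$true_length_um / d$scale),
                     numeric(1))
  expect_true(all(base_len >= 5 & base_len <= 10))

  gm2 <- generate_mito_movie("mutant_mito", 8, seed = 1)
  per2 <- split(gm2$truth, gm2$truth$object)
  base2 <- vapply(per2, function(d) mean(d$true_length_um / d$scale),
                  numeric(1))
  expect_true(all(base2 >= 1 & base2 <= 3))
  amp2 <- vapply(per2, function(d)
    (max(d$true_length_um) - min(d$true_length_um)) / mean(d$true_length_um),
    numeric(1))
  expect_equal(unname(amp2), rep(0.15, length(amp2)), tolerance = 1e-9)
})

test_that("zero oscillation amplitude gives constant true lengths", {
  gm <- generate_mito_movie(fast_preset(osc_amplitude = 0), 5, seed = 9)
  per <- split(gm$truth$true_length_um, gm$truth$object)
  for (v in per) expect_equal(sd(v), 0, tolerance = 1e-12)
})

test_that("fission events split objects and preserve the parent identity", {
  gm <- generate_mito_movie(fast_preset(event_rate = 0.4), 6, seed = 3)
  n_first <- sum(gm$truth$frame == 1)
  n_last <- sum(gm$truth$frame == max(gm$truth$frame))
  expect_gt(n_last, n_first)
  # original identities persist to the final frame
  expect_true(all(seq_len(4) %in% gm$truth$object[gm$truth$frame == 6]))
})

test_that("FRAP generator matches its closed form", {
  # full recovery returns to the prebleach level
  g1 <- generate_frap_series(1, 120, noise_sigma = 0, duration_s = 1800,
                             seed = 1)
  expect_equal(tail(g1$curve$intensity, 1), 200, tolerance = 0.2)
  # immobile: post-bleach samples constant at the floor
  g0 <- generate_frap_series(0, 180, noise_sigma = 0, seed = 1)
  post <- g0$curve$intensity[g0$truth$bleach_index:nrow(g0$curve)]
  expect_equal(post, rep(20, length(post)))
  # half-mobile at t = 15 min: 0.5 * (1 - exp(-5)) of the bleached depth
  g5 <- generate_frap_series(0.5, 180, noise_sigma = 0, seed = 1)
  b <- g5$truth$bleach_index
  t0 <- g5$curve$time_s[b]
  f_at <- approx(g5$curve$time_s - t0, g5$curve$intensity, xout = 900)$y
  frac <- (f_at - g5$truth$F0) / (g5$truth$F_pre - g5$truth$F0)
  expect_equal(frac, 0.5 * (1 - exp(-5)), tolerance = 0.002)
  expect_error(generate_frap_series(1.2, 100, seed = 1), "mobile_fraction")
  expect_error(generate_frap_series(0.5, -3, seed = 1), "tau")
})

test_that("puncta fields honor the requested counts", {
  # degenerate at 0: blank cells
  f0 <- generate_puncta_field(6, 0, noise_sigma = 0, seed = 2)
  expect_true(all(f0$truth$true_count == 0))
  expect_equal(max(f0$image) - min(f0$image), 0)
  # degenerate at 6: every cell is truth-positive under the >5 rule
  f6 <- generate_puncta_field(10, 6, seed = 2)
  expect_true(all(classify_positive(f6$truth$true_count)))
  expect_equal(sort(unique(as.vector(f6$cell_labels))), 0:10)
})

test_that("drawn counts equal an independent draw with the same seed", {
  fa <- generate_puncta_field(200, function(n) rpois(n, 4), seed = 7)
  fb <- generate_puncta_field(200, function(n) rpois(n, 10), seed = 8)
  set.seed(7); expect_identical(fa$truth$true_count, rpois(200, 4))
  set.seed(8); expect_identical(fb$truth$true_count, rpois(200, 10))
  ratio <- mean(fb$truth$true_count) / mean(fa$truth$true_count)
  expect_equal(ratio, 2.5, tolerance = 0.15)
})

test_that("generators are seeded and refuse to run without a seed", {
  expect_error(generate_mito_movie(fast_preset(), 4), "seed")
  expect_error(generate_frap_series(0.5, 100), "seed")
  expect_error(generate_puncta_field(5, 3), "seed")
  a <- generate_frap_series(0.9, 240, seed = 4)
  b <- generate_frap_series(0.9, 240, seed = 4)
  expect_identical(a$curve, b$curve)
  pa <- generate_puncta_field(5, 3, seed = 4)
  pb <- generate_puncta_field(5, 3, seed = 4)
  expect_identical(pa$image, pb$image)
})
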