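track_df <- function(y, x, length_um = 1, frame = seq_along(y)) {
  tibble::tibble(track = 1L, frame = frame, length_um = length_um,
                 centroid_y = y, centroid_x = x)
}

test_that("dynamic range is (max - min)/mean in percent", {
  expect_equal(dynamic_range(c(2, 2, 2)), 0)
  expect_equal(dynamic_range(c(0.5, 1.0, 2.0)), 100 * 1.5 / (3.5 / 3))
  # scale invariance
  set.seed(2)
  v <- runif(10, 0.5, 3)
  expect_equal(dynamic_range(v * 7.3), dynamic_range(v))
  expect_error(dynamic_range(2), "at least 2")
  expect_error(dynamic_range(c(-1, 1)), "positive")
})

test_that("displacement metrics match direct arithmetic on a random walk", {
  set.seed(5)
  y <- cumsum(rnorm(6)); x <- cumsum(rnorm(6))
  tr <- track_df(y, x)
  expect_equal(net_displacement(tr, 0.09),
               sqrt((y[6] - y[1])^2 + (x[6] - x[1])^2) * 0.09)
  expect_equal(path_length(tr, 0.09),
               sum(sqrt(diff(y)^2 + diff(x)^2)) * 0.09)
  expect_gte(path_length(tr, 0.09), net_displacement(tr, 0.09))
  # straight drift: path = net
  st <- track_df(rep(0, 11), 0:10)
  expect_equal(net_displacement(st, 0.09), 0.9)
  expect_equal(path_length(st, 0.09), 0.9)
  # out and back: positive path, zero net
  ob <- track_df(c(0, 0, 0), c(0, 5, 0))
  expect_equal(net_displacement(ob, 1), 0)
  expect_equal(path_length(ob, 1), 10)
})

test_that("directionality is the confinement ratio", {
  expect_equal(directionality(track_df(rep(0, 5), 1:5)), 1.0)
  loop <- track_df(c(0, 0, 3, 3, 0), c(0, 4, 4, 0, 0))
  expect_equal(directionality(loop), 0.0)
  # square wave: 10 right, 10 up, 10 right
  sq <- track_df(c(0, 0, 10, 10), c(0, 10, 10, 20))
  expect_equal(directionality(sq), sqrt(20^2 + 10^2) / 30, tolerance = 1e-9)
  expect_lte(directionality(sq), 1)
})

test_that("summarize_dynamics reproduces a hand-computed two-track fixture", {
  tracks <- dplyr::bind_rows(
    tibble::tibble(track = 1L, frame = 1:4, length_um = c(1, 2, 1.5, 1.5),
                   centroid_y = c(0, 0, 0, 0), centroid_x = c(0, 3, 6, 9)),
    tibble::tibble(track = 2L, frame = 1:3, length_um = c(2, 2, 2),
                   centroid_y = c(5, 8, 5), centroid_x = c(5, 5, 5)),
    tibble::tibble(track = 3L, frame = 1:2, length_um = c(1, 1),
                   centroid_y = c(0, 0), centroid_x = c(0, 1))  # too short
  )
  s <- summarize_dynamics(tracks, pixel_size_um = 1, min_track_len = 3)
  expect_equal(s$n_excluded, 1)
  expect_equal(nrow(s$tracks), 2)
  t1 <- s$tracks[s$tracks$track == 1, ]
  expect_equal(t1$mean_length_um, 1.5)
  expect_equal(t1$dynamic_range_pct, 100 * 1 / 1.5)
  expect_equal(t1$net_displacement_um, 9)
  expect_equal(t1$path_length_um, 9)
  expect_equal(t1$directionality, 1)
  t2 <- s$tracks[s$tracks$track == 2, ]
  expect_equal(t2$dynamic_range_pct, 0)
  expect_equal(t2$net_displacement_um, 0)
  expect_equal(t2$path_length_um, 6)
  expect_equal(t2$directionality, 0)
  expect_equal(s$condition$median_dynamic_range,
               median(c(100 / 1.5, 0)))
  expect_equal(s$condition$n_tracks, 2)
  # broom-style accessors
  expect_identical(tidy(s), s$tracks)
  expect_identical(glance(s), s$condition)
  expect_error(summarize_dynamics(tracks, 1, min_track_len = 5),
               "no tracks")
})

test_that("a stationary constant-length track has all dynamics metrics zero", {
  tr <- tibble::tibble(track = 1L, frame = 1:4, length_um = 2.2,
                       centroid_y = 3, centroid_x = 4)
  s <- summarize_dynamics(tr, pixel_size_um = 0.09)
  expect_equal(s$tracks$dynamic_range_pct, 0)
  expect_equal(s$tracks$net_displacement_um, 0)
  expect_equal(s$tracks$path_length_um, 0)
  expect_equal(s$tracks$directionality, 0)
  expect_equal(s$tracks$mean_length_um, 2.2)
})

test_that("generator amplitudes are recovered through the full pipeline", {
  # parameter-recovery sweep on noise-free fragmented-style movies
  for (a in c(0, 0.15, 0.5)) {
    p <- mito_preset("mutant_mito")
    p$noise_sigma <- 0
    p$osc_amplitude <- a
    if (a == 0) p$jitter_um <- 0  # static condition: no spurious dynamics
    gm <- generate_mito_movie(p, 8, seed = 11)
    obj <- segment_movie(gm$movie, mode = "midgrey")
    tr <- link_tracks(obj)
    s <- summarize_dynamics(tr, gm$movie$pixel_size_um)
    med <- s$condition$median_dynamic_range
    if (a == 0) {
      expect_lt(med, 2)  # within 2 percentage points of zero
    } else {
      expect_lt(abs(med - 100 * a) / (100 * a), 0.20)
    }
  }
})
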