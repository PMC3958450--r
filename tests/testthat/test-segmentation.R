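test_that("midgrey threshold equals the brute-force disk-scan oracle", {
  set.seed(42)
  for (case in 1:5) {
    img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    for (r in c(1, 3)) {
      expect_identical(unclass(midgrey_threshold(img, radius = r))[, ],
                       oracle_midgrey(img, r))
    }
    expect_identical(unclass(midgrey_threshold(img, 3, offset = 10))[, ],
                     oracle_midgrey(img, 3, offset = 10))
    expect_identical(
      unclass(midgrey_threshold(img, 3, min_contrast = 40))[, ],
      oracle_midgrey(img, 3, min_contrast = 40))
  }
})

test_that("midgrey threshold boundary behavior: ties, lone maxima, errors", {
  # constant image: every pixel ties with its mid-grey -> all background
  expect_false(any(midgrey_threshold(matrix(100, 20, 20))))
  # single bright pixel is forced foreground by (0 + 255)/2
  img <- matrix(0, 20, 20); img[10, 11] <- 255
  m <- midgrey_threshold(img, radius = 5)
  expect_true(m[10, 11])
  expect_equal(sum(m), 1)
  expect_error(midgrey_threshold(img, radius = 25), "dimension")
  expect_error(midgrey_threshold(img, radius = 0), "positive")
})

test_that("clean_mask removes only small components (8-connectivity)", {
  m <- matrix(FALSE, 20, 30)
  m[2:4, 2] <- TRUE                 # area 3
  m[10:14, 5:14] <- TRUE            # area 50
  expect_equal(sum(clean_mask(m, 5)), 50)
  expect_identical(clean_mask(m, 0), m)
  # checkerboard is one 8-connected component and survives min_area 2
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2 == 0)
  expect_identical(clean_mask(cb, 2)[, ], cb)
})

test_that("thinning centerline of a solid bar matches the medial axis of a rectangle", {
  m <- matrix(FALSE, 9, 56)
  m[4:6, 4:53] <- TRUE  # 50 x 3 bar
  cl <- medial_axis_centerlines(m, method = "thinning")
  expect_equal(nrow(cl), 1)
  expect_gte(nrow(cl$path[[1]]), 47)
  expect_lte(nrow(cl$path[[1]]), 50)
  # all path pixels on the middle row
  expect_true(all(cl$path[[1]][, 1] == 5))
})

test_that("centerline extraction finds one path per component", {
  m <- matrix(FALSE, 20, 60)
  m[4:6, 5:55] <- TRUE
  m[14:16, 5:55] <- TRUE
  for (method in c("geodesic", "thinning")) {
    cl <- medial_axis_centerlines(m, method = method)
    expect_equal(nrow(cl), 2)
  }
  empty <- medial_axis_centerlines(matrix(FALSE, 10, 10))
  expect_equal(nrow(empty), 0)
})

test_that("geodesic centerline spans a bar tip to tip and reports its half-width", {
  m <- matrix(FALSE, 11, 60)
  m[4:8, 6:55] <- TRUE  # 50 x 5 bar
  cl <- medial_axis_centerlines(m, method = "geodesic")
  expect_equal(nrow(cl), 1)
  p <- cl$path[[1]]
  expect_gte(max(p[, 2]) - min(p[, 2]), 47)  # spans nearly the full bar
  expect_gt(cl$r_mean_px, 1)
  expect_equal(cl$area_px, 250L)
})

test_that("ridge tracing recovers synthetic tubules", {
  blank <- matrix(50, 64, 64)
  expect_equal(nrow(ridge_centerlines(blank)), 0)

  one <- make_tubule_frame(row = 32)
  cl <- ridge_centerlines(one)
  expect_equal(nrow(cl), 1)
  # path stays within 2 px of the generating line everywhere
  expect_true(all(abs(cl$path[[1]][, 1] - 32.5) <= 2.5))

  # parallel tubules spanning the frame, axes 10 px apart
  two <- make_tubule_frame(row = 26, x0 = 1, x1 = 64) +
    make_tubule_frame(row = 36, x0 = 1, x1 = 64) - 10
  cl2 <- ridge_centerlines(two)
  expect_equal(nrow(cl2), 2)
  expect_error(ridge_centerlines(one, tubule_sigma_px = -1), "positive")
})

test_that("measure_length follows the axial/diagonal step convention", {
  axial <- cbind(rep(5, 11), 1:11)
  expect_equal(measure_length(axial, 0.09), 0.90)
  diag <- cbind(1:11, 1:11)
  expect_equal(measure_length(diag, 0.09), 10 * sqrt(2) * 0.09)
  expect_equal(measure_length(cbind(3, 4), 0.09), 0)  # single pixel
  expect_error(measure_length(axial[0, , drop = FALSE], 0.09), "empty")
  # invariance under path reversal and 90-degree rotation
  set.seed(8)
  steps <- matrix(sample(c(-1, 0, 1), 40, replace = TRUE), 20, 2)
  path <- apply(rbind(c(50, 50), steps), 2, cumsum)
  expect_equal(measure_length(path, 0.09),
               measure_length(path[nrow(path):1, ], 0.09))
  rot <- cbind(path[, 2], -path[, 1])
  expect_equal(measure_length(path, 0.09), measure_length(rot, 0.09))
})

test_that("longest-path length never decreases when pixels are added", {
  set.seed(13)
  for (case in 1:5) {
    m <- matrix(FALSE, 15, 40)
    m[7:9, 5:30] <- TRUE
    base <- mitodyn:::longest_path(which(m, arr.ind = TRUE))
    len0 <- measure_length(base, 1)
    # graft extra pixels onto the component
    m2 <- m
    m2[9:12, 18] <- TRUE
    m2[7, 31:(31 + case)] <- TRUE
    grown <- mitodyn:::longest_path(which(m2, arr.ind = TRUE))
    expect_gte(measure_length(grown, 1), len0)
  }
})

test_that("noise-free synthetic movies are segmented to the true count and lengths", {
  match_truth <- function(objects, truth) {
    merged <- lapply(seq_len(nrow(objects)), function(i) {
      tf <- truth[truth$frame == objects$frame[i], ]
      j <- which.min((tf$centroid_y - objects$centroid_y[i])^2 +
                       (tf$centroid_x - objects$centroid_x[i])^2)
      c(measured = objects$length_um[i], true = tf$true_length_um[j])
    })
    do.call(rbind, merged)
  }
  mut <- mito_preset("mutant_mito"); mut$noise_sigma <- 0
  gm <- generate_mito_movie(mut, 3, seed = 2)
  obj <- segment_movie(gm$movie, mode = "midgrey")
  expect_equal(unname(table(obj$frame)), rep(12L, 3), ignore_attr = TRUE)
  cmp <- match_truth(obj, gm$truth)
  expect_true(all(abs(cmp[, 1] - cmp[, 2]) / cmp[, 2] < 0.10))

  # control uses the full 8-frame acquisition so the oscillation spans the
  # preset's intended scale range
  ctl <- mito_preset("control_mito"); ctl$noise_sigma <- 0
  gc <- generate_mito_movie(ctl, 8, seed = 1)
  objc <- segment_movie(gc$movie, mode = "ridge")
  expect_equal(unname(table(objc$frame)), rep(6L, 8), ignore_attr = TRUE)
  cmpc <- match_truth(objc, gc$truth)
  expect_true(all(abs(cmpc[, 1] - cmpc[, 2]) / cmpc[, 2] < 0.10))
})
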