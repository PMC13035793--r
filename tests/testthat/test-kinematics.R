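test_that("the composite map has the expected anatomy", {
  cm <- composite_map()
  expect_length(cm, 15L)
  expect_equal(cm$head, 0:10)                       # 11 facial landmarks
  expect_length(cm$left_hand, 3L)                   # thumb/index/pinky
  expect_length(cm$right_foot, 2L)                  # heel + foot index
  singletons <- c("left_shoulder", "right_shoulder", "left_elbow",
                  "right_elbow", "left_wrist", "right_wrist",
                  "left_knee", "right_knee", "left_ankle", "right_ankle")
  expect_true(all(lengths(cm[singletons]) == 1L))
  expect_false(any(c(23L, 24L) %in% unlist(cm)))    # hips are root only
})

test_that("composites are unweighted member centroids", {
  x <- matrix(0.5, 3, 33)
  x[, c(17, 19, 21) + 1] <- matrix(c(0.1, 0.2, 0.6), 3, 3, byrow = TRUE)
  s <- make_session(n = 3, x = x)
  comp <- to_composites(s)
  expect_equal(comp$x[, "left_hand"], rep(0.3, 3))
  # identical facial points -> centroid equals the shared point
  expect_equal(comp$x[, "head"], rep(0.5, 3))
  # singleton equals the raw landmark
  expect_equal(comp$x[, "left_shoulder"], s$x[, 12])
})

test_that("the pelvic root frame subtracts the hip midpoint and rejects
           common-mode translation", {
  x <- matrix(0.5, 2, 33); y <- matrix(0.5, 2, 33)
  x[, 24] <- 0.4; x[, 25] <- 0.6; y[, 24] <- y[, 25] <- 0.6
  x[, 1:11] <- 0.5; y[, 1:11] <- 0.3           # head raw (0.5, 0.3)
  s <- make_session(n = 2, x = x, y = y)
  rel <- to_root_frame(to_composites(s), s)
  expect_equal(rel$x[, "head"], rep(0.0, 2))
  expect_equal(rel$y[, "head"], rep(-0.3, 2))

  # adding any per-frame common translation leaves the frame unchanged
  sw <- wiggle_session(n = 50)
  rel0 <- to_root_frame(to_composites(sw), sw)
  set.seed(9)
  dx <- rnorm(50, 0, 0.05); dy <- rnorm(50, 0, 0.05)
  st <- make_session(n = 50, x = sw$x + dx, y = sw$y + dy)
  rel1 <- to_root_frame(to_composites(st), st)
  expect_equal(rel1$x, rel0$x, tolerance = 1e-12)
  expect_equal(rel1$y, rel0$y, tolerance = 1e-12)
})

# Explicit block means and pairwise distances, the slow way.
displacement_oracle <- function(xy, w) {
  nb <- nrow(xy) %/% w
  means <- t(sapply(seq_len(nb), function(b)
    colMeans(xy[((b - 1) * w + 1):(b * w), , drop = FALSE])))
  sapply(seq_len(nb - 1), function(i)
    sqrt(sum((means[i + 1, ] - means[i, ])^2)))
}

test_that("windowed displacement equals the brute-force oracle at all
           window sizes", {
  set.seed(3)
  xy <- cbind(rnorm(30), rnorm(30))
  for (w in c(5L, 10L, 15L)) {
    long <- cbind(rnorm(8 * w), rnorm(8 * w))
    expect_equal(windowed_displacement(long, w), displacement_oracle(long, w),
                 tolerance = 1e-12)
  }
  expect_equal(windowed_displacement(xy, 5L), displacement_oracle(xy, 5L),
               tolerance = 1e-12)
  # trailing partial block dropped
  xy33 <- cbind(rnorm(33), rnorm(33))
  expect_length(windowed_displacement(xy33, 5L), 5L)
  expect_error(windowed_displacement(xy[1:9, ], 5L), "too short")
})

test_that("uniform velocity gives the closed-form displacement total", {
  v <- 1e-5
  n <- 9000L
  xy <- cbind(v * (seq_len(n) - 1), rep(0, n))
  d <- windowed_displacement(xy, 5L)
  expect_length(d, 1799L)
  expect_equal(d, rep(5 * v, 1799L), tolerance = 1e-12)
  expect_equal(activity_index(d), 8995 * v, tolerance = 1e-9)
  # constant trajectory: all displacements zero
  expect_equal(windowed_displacement(matrix(0.4, 20, 2), 5L), rep(0, 3))
})

test_that("activity and variability indices are the sum and sample SD of
           the displacement series", {
  expect_equal(activity_index(c(0.001, 0.002, 0.003)), 0.006)
  expect_equal(activity_index(rep(0, 10)), 0)
  expect_error(activity_index(numeric(0)))

  expect_equal(variability_index(c(0, 0.002)), 0.002 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(variability_index(rep(0.01, 5)), 0)
  expect_error(variability_index(0.01))
  set.seed(5)
  d <- rexp(40, 1000)
  two_pass <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  expect_equal(variability_index(d), two_pass, tolerance = 1e-12)
})

test_that("the global index sums the 15 regional indices", {
  act <- setNames(rep(0.001, 15), region_names())
  expect_equal(global_activity(act), 0.015)
  expect_equal(global_activity(act * 0), 0)
  expect_error(global_activity(act[-1]), "missing")
})

test_that("height normalization divides by height and is homogeneous", {
  expect_equal(normalize_by_height(0.0426, 130), 3.276923e-4, tolerance = 1e-6)
  expect_equal(normalize_by_height(0, 150), 0)
  expect_equal(normalize_by_height(0.03, 100), 2 * normalize_by_height(0.03, 200))
  expect_error(normalize_by_height(0.03, -1), "positive")
})

test_that("features are translation invariant and homogeneous of degree one", {
  s <- wiggle_session(n = 100)
  f0 <- extract_features(s)
  # common translation: exact invariance of every feature
  st <- make_session(n = 100, x = s$x + 0.123, y = s$y - 0.2)
  ft <- extract_features(st)
  expect_equal(ft$activity, f0$activity, tolerance = 1e-12)
  expect_equal(ft$variability, f0$variability, tolerance = 1e-12)
  # scaling all coordinates by c scales every index by exactly c
  c3 <- 3
  sc <- make_session(n = 100, x = s$x * c3, y = s$y * c3)
  fc <- extract_features(sc)
  expect_equal(fc$activity, c3 * f0$activity, tolerance = 1e-10)
  expect_equal(fc$variability, c3 * f0$variability, tolerance = 1e-10)
  expect_equal(fc$global, c3 * f0$global, tolerance = 1e-10)
})

test_that("every subject yields 15 activity + 15 variability + 1 global
           feature, reproducibly across window sizes", {
  s <- wiggle_session(n = 90)
  for (w in c(5L, 10L, 15L)) {
    f <- extract_features(s, w = w)
    expect_length(f$activity, 15L)
    expect_length(f$variability, 15L)
    expect_length(f$global, 1L)
    expect_equal(f$global, sum(f$activity))
    expect_identical(extract_features(s, w = w), f)  # reproducible
  }
})
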