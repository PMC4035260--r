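test_that("root transform maps rows to sqrt of their L1 normalization", {
  # one-hot rows are fixed points
  v <- matrix(0, 2, 128); v[1, 5] <- 3; v[2, 100] <- 0.01
  d <- palmvein:::descriptor_set(
    tibble::tibble(x = c(1, 2), y = c(1, 2), scale = c(1, 1),
                   orientation = c(0, 0), response = c(0, 0)), v)
  r <- root_sift(d)
  expect_equal(r$vectors[1, 5], 1)
  expect_equal(r$vectors[2, 100], 1)
  expect_equal(rowSums(r$vectors^2), c(1, 1), tolerance = 1e-12)
  # uniform rows map to sqrt(1/128) everywhere
  vu <- matrix(2.5, 1, 128)
  du <- palmvein:::descriptor_set(
    tibble::tibble(x = 1, y = 1, scale = 1, orientation = 0, response = 0), vu)
  expect_equal(root_sift(du)$vectors[1, ], rep(sqrt(1 / 128), 128),
               tolerance = 1e-12)
  expect_error(root_sift(palmvein:::descriptor_set(du$keypoints, -vu)),
               "nonnegative")
})

test_that("zero-mass rows are dropped with their keypoints, quietly", {
  v <- rbind(matrix(runif(128), 1), matrix(0, 1, 128))
  d <- palmvein:::descriptor_set(
    tibble::tibble(x = c(1, 2), y = c(1, 2), scale = c(1, 1),
                   orientation = c(0, 0), response = c(0, 0)), v)
  expect_message(r <- root_sift(d), "zero-mass")
  expect_length(r, 1)
  expect_equal(r$keypoints$x, 1)
})

test_that("Euclidean distance on root-transformed rows equals the Hellinger identity", {
  set.seed(31)
  for (i in 1:50) {
    x <- random_raw_descriptors(1, 1000 + i)[1, ]
    y <- random_raw_descriptors(1, 2000 + i)[1, ]
    x[1] <- x[1] + 0.1; y[2] <- y[2] + 0.1 # nonzero mass
    xh <- x / sum(x); yh <- y / sum(y)
    d2 <- sum((sqrt(xh) - sqrt(yh))^2)
    expect_equal(d2, 2 - 2 * hellinger(xh, yh), tolerance = 1e-10)
  }
})

test_that("hellinger kernel: identity, disjoint support, symmetry, oracle", {
  set.seed(7)
  x <- runif(128); x <- x / sum(x)
  expect_equal(hellinger(x, x), 1, tolerance = 1e-10)
  a <- c(rep(1 / 64, 64), rep(0, 64))
  b <- c(rep(0, 64), rep(1 / 64, 64))
  expect_identical(hellinger(a, b), 0)
  y <- runif(128); y <- y / sum(y)
  brute <- 0
  for (i in 1:128) brute <- brute + sqrt(x[i] * y[i])
  expect_equal(hellinger(x, y), brute, tolerance = 1e-12)
  expect_equal(hellinger(x, y), hellinger(y, x))
  expect_error(hellinger(x * 2, y), "L1")
  expect_error(hellinger(-x, y), "nonnegative")
})

test_that("ratio-test matching: self-match, tiny gallery, non-unit input", {
  a <- random_descriptor_set(8, 11)
  m <- match_descriptors(a, a)
  expect_equal(m$index_b, m$index_a)
  expect_lt(max(m$distance), 1e-6)
  expect_lt(max(m$ratio), 1e-4)
  # single-row gallery: no second-closest, no matches
  b1 <- palmvein:::subset_descriptor_set(a, 1)
  expect_identical(nrow(match_descriptors(a, b1)), 0L)
  bad <- palmvein:::descriptor_set(a$keypoints, a$vectors * 2)
  expect_error(match_descriptors(a, bad), "unit-norm")
})

test_that("matching agrees with the brute-force all-pairs oracle", {
  set.seed(55)
  for (trial in 1:10) {
    a <- random_descriptor_set(12, 300 + trial)
    b <- random_descriptor_set(15, 400 + trial)
    m <- match_descriptors(a, b, match_params(dist_ratio = 0.8))
    # oracle: explicit distance matrix, nearest two by sorting
    D <- as.matrix(dist(rbind(a$vectors, b$vectors)))[1:12, 12 + (1:15)]
    exp_pairs <- list()
    for (i in 1:12) {
      ord <- order(D[i, ])
      d1 <- D[i, ord[1]]; d2 <- D[i, ord[2]]
      ratio <- if (d2 <= 0) 1 else d1 / d2
      if (ratio < 0.8) exp_pairs[[length(exp_pairs) + 1]] <-
          c(i, ord[1], d1, ratio)
    }
    exp_m <- do.call(rbind, exp_pairs)
    if (is.null(exp_m)) {
      expect_identical(nrow(m), 0L)
    } else {
      expect_equal(m$index_a, exp_m[, 1])
      expect_equal(m$index_b, exp_m[, 2])
      expect_equal(m$distance, exp_m[, 3], tolerance = 1e-10)
      expect_equal(m$ratio, exp_m[, 4], tolerance = 1e-10)
    }
  }
})

test_that("duplicate gallery descriptors at distance zero are rejected", {
  a <- random_descriptor_set(4, 21)
  b <- palmvein:::descriptor_set(
    a$keypoints[c(1, 1, 2, 3), ], a$vectors[c(1, 1, 2, 3), ])
  m <- match_descriptors(a, b)
  # row 1 of a finds two copies of itself: d2 = 0 -> ratio 1 -> rejected
  expect_false(1 %in% m$index_a)
})

test_that("matching is gain-invariant and monotone in the ratio threshold", {
  raw <- random_raw_descriptors(20, 91)
  kp <- tibble::tibble(x = 1:20, y = 1:20, scale = rep(2, 20),
                       orientation = rep(0, 20), response = rep(0, 20))
  d1 <- suppressMessages(root_sift(palmvein:::descriptor_set(kp, raw)))
  d2 <- suppressMessages(root_sift(palmvein:::descriptor_set(kp, raw * 37.5)))
  expect_equal(d1$vectors, d2$vectors, tolerance = 1e-12)
  f <- fixture_features()
  g <- extract_features(render_sample(fixture_identity(), std_acq(rotation = 5, seed = 8))$image)
  m_all <- match_descriptors(f$rootsift, g$rootsift, match_params(1))
  for (r in c(0.6, 0.8)) {
    m_r <- match_descriptors(f$rootsift, g$rootsift, match_params(r))
    expect_true(all(m_r$index_a %in% m_all$index_a))
    expect_true(all(m_r$ratio < r))
  }
})
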