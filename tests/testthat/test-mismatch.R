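fake_matches <- function(xa, ya, xb, yb) {
  palmvein:::as_match_set(tibble::tibble(
    index_a = seq_along(xa), index_b = seq_along(xa),
    x_a = xa, y_a = ya, x_b = xb, y_b = yb,
    distance = 0.1, ratio = 0.5
  ))
}

test_that("neighbor filter keeps self-pairs and cancels pure translation", {
  m1 <- disk_mask(128, c(64, 64), 40)
  pts <- cbind(runif(15, 30, 98), runif(15, 30, 98))
  mm <- fake_matches(pts[, 1], pts[, 2], pts[, 1], pts[, 2])
  out <- neighbor_filter(mm, m1, m1)
  expect_true(all(out$label == "kept"))
  expect_true(all(out$neighbor_distance == 0))
  # translate the second image (mask and keypoints) by the same offset
  m2 <- disk_mask(128, c(64 + 17, 64 - 9), 40)
  mt <- fake_matches(pts[, 1], pts[, 2], pts[, 1] - 9, pts[, 2] + 17)
  out2 <- neighbor_filter(mt, m1, m2)
  expect_true(all(out2$label == "kept"))
  expect_equal(out2$neighbor_distance, rep(0, 15), tolerance = 1e-8)
})

test_that("neighbor filter removes displaced pairs per the worked example", {
  # centroids both at (row 100, col 100); keypoints displaced by 30 px with
  # threshold 15 px (pixel units) -> removed
  m <- disk_mask(200, c(100, 100), 50)
  mm <- fake_matches(120, 100, 120, 130)
  out <- neighbor_filter(mm, m, m,
                         neighbor_filter_config(15, scale_normalize = FALSE))
  expect_equal(out$neighbor_distance, 30)
  expect_identical(out$label, "removed_neighbor")
  expect_error(neighbor_filter(mm, palm_mask(matrix(FALSE, 5, 5)), m), "empty")
})

test_that("scale normalization makes the neighbor test invariant to rescaling", {
  m1 <- disk_mask(128, c(64, 64), 30)
  m2 <- disk_mask(256, c(128, 128), 60) # same scene at 2x scale
  pts <- cbind(runif(10, 40, 88), runif(10, 40, 88))
  mm <- fake_matches(pts[, 1], pts[, 2],
                     (pts[, 1] - 64) * 2 + 128, (pts[, 2] - 64) * 2 + 128)
  out <- neighbor_filter(mm, m1, m2, neighbor_filter_config(0.05))
  expect_true(all(out$neighbor_distance <= 0.05)) # quantization only
  expect_true(all(out$label == "kept"))
})

test_that("3x3 LBP codes follow the stated sign and bit-order convention", {
  expect_identical(lbp_code(matrix(5, 3, 3)), 255)
  # clockwise from top-left: [6,7,8,5,4,3,2,9] around center 6
  p <- matrix(0, 3, 3)
  p[2, 2] <- 6
  p[cbind(c(1, 1, 1, 2, 3, 3, 3, 2), c(1, 2, 3, 3, 3, 2, 1, 1))] <-
    c(6, 7, 8, 5, 4, 3, 2, 9)
  expect_identical(lbp_code(p), 135)
  q <- matrix(0, 3, 3); q[2, 2] <- 255
  expect_identical(lbp_code(q), 0)
})

test_that("uniform LBP histograms conserve mass and ignore additive offsets", {
  cfg <- lbp_filter_config(patch_size = 20)
  # constant window: code 255 is uniform, one bin holds all mass
  h <- uniform_lbp_histogram(matrix(90, 64, 64), c(32, 32), cfg)
  expect_identical(sum(h), 324L)
  expect_identical(sum(h > 0), 1L)
  set.seed(12)
  img <- matrix(sample(40:160, 64 * 64, replace = TRUE), 64)
  h1 <- uniform_lbp_histogram(img, c(32, 32), cfg)
  expect_identical(sum(h1), 324L)
  expect_identical(uniform_lbp_histogram(img + 40, c(32, 32), cfg), h1)
  expect_error(uniform_lbp_histogram(img, c(3, 3), cfg), "out of bounds")
})

test_that("the histogram distance matches its closed forms and an oracle", {
  h <- c(rep(3, 10), rep(0, 49))
  expect_identical(lbp_histogram_distance(h, h), 0)
  a <- c(12, rep(0, 58)); b <- c(0, 12, rep(0, 57))
  expect_equal(lbp_histogram_distance(a, b), 24) # 2m for disjoint one-hots
  set.seed(3)
  h1 <- rmultinom(1, 900, runif(59))[, 1]
  h2 <- rmultinom(1, 900, runif(59))[, 1]
  brute <- 0
  for (i in 1:59) {
    if (h1[i] + h2[i] > 0) brute <- brute + (h1[i] - h2[i])^2 / (h1[i] + h2[i])
  }
  expect_equal(lbp_histogram_distance(h1, h2), brute, tolerance = 1e-12)
  expect_equal(lbp_histogram_distance(h1, h2, "l1"), sum(abs(h1 - h2)))
  expect_equal(lbp_histogram_distance(h1, h2, "intersection"),
               900 - sum(pmin(h1, h2)))
  expect_error(lbp_histogram_distance(h1, h2[1:10]), "equal bin")
})

test_that("LBP filter keeps identical-texture pairs and is inert at infinite threshold", {
  set.seed(21)
  img <- matrix(sample(30:220, 128 * 128, replace = TRUE), 128)
  mm <- fake_matches(c(40, 60, 80), c(40, 70, 90), c(40, 60, 80), c(40, 70, 90))
  out <- lbp_filter(mm, img, img)
  expect_true(all(out$label == "kept"))
  expect_true(all(out$lbp_distance == 0))
  # +Inf threshold leaves in-bounds labels unchanged on distinct textures
  img2 <- matrix(sample(30:220, 128 * 128, replace = TRUE), 128)
  inert <- lbp_filter(mm, img, img2, lbp_filter_config(distance_threshold = Inf))
  expect_true(all(inert$label == "kept"))
  # out-of-bounds patch is removed conservatively with a reason
  edge <- lbp_filter(fake_matches(2, 2, 60, 60), img, img2)
  expect_identical(edge$label, "removed_lbp")
  expect_match(edge$reason, "out of bounds")
})

test_that("a pair joining independent noise textures fails a genuine-calibrated threshold", {
  # genuine-pair distance distribution: same texture re-observed with noise
  set.seed(77)
  base <- matrix(sample(60:200, 128 * 128, replace = TRUE), 128)
  gen_d <- vapply(1:40, function(i) {
    noisy <- pmin(pmax(base + matrix(round(rnorm(128 * 128, 0, 6)), 128), 0), 255)
    ctr <- c(runif(1, 30, 98), runif(1, 30, 98))
    lbp_histogram_distance(uniform_lbp_histogram(base, ctr),
                           uniform_lbp_histogram(noisy, ctr))
  }, 0)
  thr <- quantile(gen_d, 0.05)
  indep <- matrix(sample(60:200, 128 * 128, replace = TRUE), 128)
  planted <- lbp_filter(fake_matches(64, 64, 64, 64), base, indep,
                        lbp_filter_config(distance_threshold = thr))
  expect_identical(planted$label, "removed_lbp")
})

test_that("hierarchical filter is the exact composition and removes planted outliers", {
  expect_identical(nrow(hierarchical_filter(
    fake_matches(numeric(0), numeric(0), numeric(0), numeric(0)),
    disk_mask(64, c(32, 32), 20), disk_mask(64, c(32, 32), 20),
    matrix(0, 64, 64), matrix(0, 64, 64)
  )), 0L)

  id <- fixture_identity()
  fa <- fixture_features()
  fb <- extract_features(render_sample(id, std_acq(rotation = 5, seed = 23))$image)
  m <- match_descriptors(fa$rootsift, fb$rootsift)
  # plant 20 outliers pairing far-apart locations
  set.seed(4)
  ia <- which(fa$rootsift$keypoints$y < quantile(fa$rootsift$keypoints$y, 0.3))
  ib <- which(fb$rootsift$keypoints$y > quantile(fb$rootsift$keypoints$y, 0.7))
  pick_a <- sample(ia, 20, replace = TRUE); pick_b <- sample(ib, 20, replace = TRUE)
  planted <- tibble::tibble(
    index_a = pick_a, index_b = pick_b,
    x_a = fa$rootsift$keypoints$x[pick_a], y_a = fa$rootsift$keypoints$y[pick_a],
    x_b = fb$rootsift$keypoints$x[pick_b], y_b = fb$rootsift$keypoints$y[pick_b],
    distance = 0.5, ratio = 0.7
  )
  combined <- palmvein:::as_match_set(dplyr::bind_rows(m, planted))
  out <- hierarchical_filter(combined, fa$mask, fb$mask, fa$image, fb$image)
  planted_rows <- seq(nrow(m) + 1, nrow(m) + 20)
  expect_gte(sum(out$label[planted_rows] != "kept"), 18)
  # composition order: neighbor then LBP, exactly
  two_step <- lbp_filter(
    neighbor_filter(combined, fa$mask, fb$mask),
    fa$image, fb$image
  )
  expect_identical(out$label, two_step$label)
  # anti-extensive and idempotent on its own output
  expect_lte(sum(out$label == "kept"), nrow(combined))
  again <- hierarchical_filter(out, fa$mask, fb$mask, fa$image, fb$image)
  expect_identical(again$label, out$label)
})
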