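test_that("otsu threshold equals the exhaustive-search maximizer", {
  set.seed(101)
  for (i in 1:25) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
  # bimodal images with unequal masses
  for (i in 1:10) {
    img <- matrix(sample(c(rnorm(500, 60, 10), rnorm(300, 190, 15)), 1024,
                         replace = TRUE), 32)
    img <- pmin(pmax(round(img), 0), 255)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("otsu tie-break picks the smallest maximizer and degenerate input errors", {
  img <- matrix(c(rep(50, 90), rep(200, 54)), 12)
  expect_identical(otsu_threshold(img), 50L)
  expect_error(otsu_threshold(matrix(7, 10, 10)), "degenerate")
})

test_that("otsu restricted to an ROI uses only that region's histogram", {
  img <- matrix(0, 32, 32)
  img[1:16, ] <- 50; img[17:32, ] <- 200
  roi <- palm_mask(row(img) <= 16 | col(img) <= 5)
  expect_identical(otsu_threshold(img, roi), oracle_otsu(img[roi$bits]))
})

test_that("segment_palm recovers a bright shape and drops specks", {
  img <- toy_hand_image()
  m <- segment_palm(img)
  expect_identical(m$bits, img > 20)
  # add 5 isolated bright specks well under 20 px each
  img2 <- img
  set.seed(5)
  for (k in 1:5) {
    r <- sample(2:10, 1); c <- sample(seq(2, 90, by = 20), 1)
    img2[r:(r + 2), c:(c + 2)] <- 200
  }
  m2 <- segment_palm(img2)
  lab <- oracle_components(img2 > 20)
  main <- which.max(tabulate(lab[lab > 0]))
  expect_identical(m2$bits, lab == main)
  expect_error(segment_palm(matrix(12, 96, 96)), "no palm")
})

test_that("palm_mask invariants hold after segmentation", {
  m <- segment_palm(toy_hand_image())
  idx <- which(m$bits, arr.ind = TRUE)
  expect_equal(m$centroid, c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1))
  expect_identical(m$area, nrow(idx))
  lab <- oracle_components(m$bits)
  expect_identical(max(lab), 1L)
})

test_that("crop_wrist cuts only beyond the radial threshold", {
  # disk untouched when R exceeds its radius
  disk <- disk_mask(120, c(60, 60), 30)
  expect_identical(crop_wrist(disk, 3)$bits, disk$bits)
  # disk + forearm stub: stub pixels beyond R removed, disk intact
  bits <- disk_mask(160, c(60, 80), 40)$bits
  bits[61:160, 73:88] <- TRUE
  m <- palm_mask(bits)
  R <- 1.4 * sqrt(m$area / pi)
  cropped <- crop_wrist(m, 1.4)
  d <- sqrt((row(bits) - 1 - m$centroid[1])^2 + (col(bits) - 1 - m$centroid[2])^2)
  expect_identical(cropped$bits, bits & d <= R)
  expect_true(all(cropped$bits <= m$bits))
  expect_lte(cropped$area, m$area)
  # monotone: larger factor keeps supersets; infinite factor is identity
  expect_true(all(crop_wrist(m, 1.2)$bits <= cropped$bits))
  expect_identical(crop_wrist(m, 100)$bits, m$bits)
  expect_error(crop_wrist(palm_mask(matrix(FALSE, 5, 5)), 1), "empty")
})

test_that("DoG response is null on constants and matches the closed-form kernel", {
  expect_lt(max(abs(dog_response(matrix(100, 64, 64)))), 1e-6 * 255)
  n <- 129
  imp <- matrix(0, n, n); imp[65, 65] <- 255
  resp <- dog_response(imp, 2, 1.6)
  xs <- (-64):64
  ana <- 255 * (outer(xs, xs, function(a, b) oracle_gauss2(b, a, 2)) -
                  outer(xs, xs, function(a, b) oracle_gauss2(b, a, 3.2)))
  expect_lt(max(abs(resp - ana)), 1e-8)
})

test_that("DoG amplitude gain on a sinusoid follows the Gaussian transfer function", {
  n <- 256
  for (k in c(8, 13, 26)) { # integer periods over the frame
    f <- k / n
    x <- 0:(n - 1)
    sig <- matrix(rep(127.5 + 100 * sin(2 * pi * f * x), each = n), n)
    resp <- dog_response(sig, 2, 1.6)
    # least-squares fit of the interior response row to the sin/cos pair
    r <- resp[n / 2, 41:216]; xi <- x[41:216]
    co <- coef(lm(r ~ sin(2 * pi * f * xi) + cos(2 * pi * f * xi)))
    gain <- sqrt(co[2]^2 + co[3]^2) / 100
    ana <- exp(-2 * pi^2 * 2^2 * f^2) - exp(-2 * pi^2 * 3.2^2 * f^2)
    expect_lt(abs(gain - ana) / ana, 0.02)
  }
})

test_that("dog_enhance rescales over mask pixels and zeroes the background", {
  img <- toy_hand_image()
  m <- segment_palm(img)
  out <- dog_enhance(img, m)
  expect_true(all(out[!m$bits] == 0))
  expect_gte(min(out[m$bits]), 0)
  expect_lte(max(out[m$bits]), 255)
  # flat response inside mask maps to 128
  flat <- dog_enhance(matrix(77, 96, 96), m)
  expect_true(all(flat[m$bits] == 128))
})

test_that("equalize applies the CDF map and preserves rank order", {
  m <- palm_mask(matrix(TRUE, 10, 10))
  img <- matrix(c(rep(100, 30), rep(200, 70)), 10)
  out <- equalize(img, m)
  expect_setequal(unique(as.vector(out)), c(round(255 * 0.3), 255))
  # constant region stays constant
  expect_true(all(equalize(matrix(42, 10, 10), m) ==
                    equalize(matrix(42, 10, 10), m)[1, 1]))
  # uniformly distributed input is (nearly) a fixed point
  u <- matrix(rep(0:255, length.out = 256 * 256), 256)
  mu <- palm_mask(matrix(TRUE, 256, 256))
  eq <- equalize(u, mu)
  expect_lte(max(abs(eq - u)), 1)
  # rank order preserved, also under a strictly increasing relabeling
  set.seed(9)
  img2 <- matrix(sample(0:200, 100, replace = TRUE), 10)
  base <- equalize(img2, m)
  relab <- equalize(pmin(round(img2 * 1.2) + 5, 255), m)
  expect_true(all(diff(base[order(img2)]) >= 0))
  expect_true(all(diff(relab[order(img2)]) >= 0))
})

test_that("full preprocessing raises keypoint yield and is deliberately not idempotent", {
  img <- fixture_sample()
  pp <- preprocess(img)
  expect_true(all(pp$image[!pp$mask$bits] == 0))
  raw_kp <- length(detect_sift(img, n_features = Inf))
  enh_kp <- length(detect_sift(pp$image, pp$mask, n_features = Inf))
  expect_gt(enh_kp, raw_kp)
  # a second enhancement pass changes the image (histogram re-equalization)
  pp2 <- preprocess(pp$image)
  expect_false(identical(pp$image, pp2$image))
})
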