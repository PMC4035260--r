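# Shared fixtures. Heavy seeded artifacts (the 20x4 benchmark, the
# robustness grid, a small gallery) are computed once per test run and
# cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# study-conditions acquisition with a given pose
std_acq <- function(rotation = 0, scale = 1, perspective_tilt = 0, seed = 1) {
  acquisition_spec(
    rotation = rotation, scale = scale, perspective_tilt = perspective_tilt,
    illumination_gradient = 0.3, blur_sigma = 1, noise_sigma = 4, seed = seed
  )
}

fixture_identity <- function() cached("identity", generate_identity(42))

fixture_sample <- function() {
  cached("sample", render_sample(fixture_identity(), std_acq(seed = 7))$image)
}

fixture_features <- function() {
  cached("features", extract_features(fixture_sample()))
}

fixture_small_gallery <- function() {
  cached("small_gallery", generate_gallery(3, 2, master_seed = 77))
}

fixture_benchmark <- function() {
  cached("benchmark", vein_benchmark(20, 4, master_seed = 1))
}

fixture_grid <- function() {
  cached("grid", robustness_grid(master_seed = 1))
}

# a bright hand-like blob (palm disk + one finger) on dark background
toy_hand_image <- function(size = 96, fg = 180, bg = 20) {
  img <- matrix(bg, size, size)
  d2 <- (row(img) - 1 - size * 0.55)^2 + (col(img) - 1 - size / 2)^2
  img[d2 <= (size * 0.25)^2] <- fg
  img[(row(img) - 1) >= size * 0.15 & (row(img) - 1) <= size * 0.55 &
        abs(col(img) - 1 - size / 2) <= size * 0.06] <- fg
  img
}
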