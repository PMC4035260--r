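#' Gaussian smoothing and difference-of-Gaussians response
#'
#' Convolution is separable with reflective ("mirror") border padding and an
#' analytic Gaussian kernel sampled out to 6 standard deviations, so the
#' discrete impulse response agrees with the continuous kernel
#' \deqn{G(x, y; \sigma) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/2\sigma^2}}
#' to well below 1e-8.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  w <- gauss_kernel_1d(sigma)
  conv_sep(img, w)
}

gauss_kernel_1d <- function(sigma, radius = ceiling(6 * sigma)) {
  x <- (-radius):radius
  exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

# mirror-pad indices: offset k beyond edge reflects across the edge pixel
reflect_idx <- function(n, r) {
  idx <- c(rev(seq_len(r)) + 1L, seq_len(n), n - seq_len(r))
  # for very small n the reflection can run out of range; fold repeatedly
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
  }
  idx
}

conv_sep <- function(m, w) {
  r <- (length(w) - 1L) / 2L
  # columns
  p <- m[, reflect_idx(ncol(m), r), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(w)) {
    out <- out + w[k] * p[, k:(k + ncol(m) - 1L), drop = FALSE]
  }
  # rows
  p <- out[reflect_idx(nrow(m), r), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(w)) {
    out <- out + w[k] * p[k:(k + nrow(m) - 1L), , drop = FALSE]
  }
  out
}

#' @describeIn gaussian_blur signed band-pass response
#'   `Gaussian(sigma1) - Gaussian(sigma2)` with `sigma2 = ratio * sigma1`
#'   (the less-blurred version minus the more-blurred one). The kernel sums
#'   to zero, so constant images produce a (numerically) zero response.
#' @param sigma1 standard deviation of the narrower Gaussian.
#' @param ratio scale ratio `sigma2 / sigma1`, must exceed 1.
#' @export
dog_response <- function(img, sigma1 = 2, ratio = 1.6) {
  stopifnot(ratio > 1, sigma1 > 0)
  img <- check_image(img)
  gaussian_blur(img, sigma1) - gaussian_blur(img, ratio * sigma1)
}
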