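#' Preprocessing configuration
#'
#' @param crop_factor wrist-crop radius multiplier: foreground farther than
#'   `crop_factor * sqrt(area / pi)` from the palm centroid is removed.
#' @param dog_sigma standard deviation (pixels) of the narrower Gaussian of
#'   the band-pass difference filter.
#' @param dog_ratio scale ratio of the two Gaussians (> 1); 1.6 approximates
#'   the Laplacian-of-Gaussian.
#' @param he_scope `"mask_only"` (default) restricts histogram equalization
#'   to palm pixels so the dark background does not skew the CDF;
#'   `"full_frame"` uses every pixel.
#' @param min_area_frac minimum foreground fraction of the frame below which
#'   segmentation fails with "no palm found".
#' @param fill_holes,keep_largest robustness switches for interior specular
#'   holes and disconnected specks.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_factor = 1.8, dog_sigma = 2, dog_ratio = 1.6,
                              he_scope = c("mask_only", "full_frame"),
                              min_area_frac = 0.02, fill_holes = TRUE,
                              keep_largest = TRUE) {
  stopifnot(crop_factor > 0, dog_sigma > 0, dog_ratio > 1,
            min_area_frac >= 0, min_area_frac < 1)
  structure(
    list(
      crop_factor = crop_factor, dog_sigma = dog_sigma, dog_ratio = dog_ratio,
      he_scope = match.arg(he_scope), min_area_frac = min_area_frac,
      fill_holes = fill_holes, keep_largest = keep_largest
    ),
    class = "preprocess_config"
  )
}

#' Otsu threshold of an intensity histogram
#'
#' Finds the integer threshold `t` maximizing the between-class variance of
#' the 8-bit histogram, with classes `<= t` and `> t`. Ties are broken by the
#' smallest maximizing `t`.
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @param roi optional [palm_mask]; the histogram is restricted to its
#'   foreground.
#' @return integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(img, roi = NULL) {
  img <- check_image(img)
  vals <- if (is.null(roi)) as.vector(img) else img[roi$bits]
  if (!length(vals)) abort("empty region: cannot compute a threshold")
  vals <- round(vals)
  if (length(unique(vals)) < 2) {
    abort("degenerate histogram (single intensity value): input is unsegmentable")
  }
  h <- tabulate(vals + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * lev)
  mt <- m0[256]
  w1 <- 1 - w0
  # between-class variance; undefined where either class is empty
  num <- (mt * w0 - m0)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, -Inf)
  as.integer(which.max(bcv) - 1L)
}

#' Segment the whole palm
#'
#' Thresholds the frame with [otsu_threshold()] (foreground = intensities
#' strictly above the threshold, the bright side under NIR illumination:
#' the threshold is the upper edge of the background class), keeps the
#' largest connected component, and fills interior holes.
#'
#' @inheritParams otsu_threshold
#' @param cfg a [preprocess_config()].
#' @return a [palm_mask].
#' @export
segment_palm <- function(img, cfg = preprocess_config()) {
  img <- check_image(img)
  t <- tryCatch(otsu_threshold(img), error = function(e) {
    abort("no palm found: image has a degenerate histogram")
  })
  bits <- round(img) > t
  if (cfg$keep_largest) bits <- largest_component(bits)
  if (cfg$fill_holes) bits <- fill_holes(bits)
  if (sum(bits) < cfg$min_area_frac * length(bits)) {
    abort("no palm found: foreground below minimum area fraction")
  }
  palm_mask(bits)
}

#' Crop the wrist/forearm region
#'
#' Clears foreground pixels whose Euclidean distance from the mask centroid
#' exceeds `R = crop_factor * sqrt(area / pi)`, then re-finalizes the mask
#' (largest component, recomputed centroid and area). The radial cut retains
#' the fingers of a typical hand silhouette while removing the forearm stub,
#' whose pixels lie farthest from the centroid.
#'
#' @param mask a [palm_mask] with nonzero area.
#' @param crop_factor positive radius multiplier.
#' @return a [palm_mask]; its foreground is a subset of the input foreground.
#' @export
crop_wrist <- function(mask, crop_factor = 1.8) {
  stopifnot(inherits(mask, "palm_mask"), crop_factor > 0)
  if (mask$area == 0) abort("empty mask: nothing to crop")
  R <- crop_factor * mask_radius(mask)
  d2 <- (row(mask$bits) - 1 - mask$centroid[1])^2 +
        (col(mask$bits) - 1 - mask$centroid[2])^2
  bits <- mask$bits & (d2 <= R^2)
  if (!any(bits)) abort("crop_factor too small: crop removed the entire palm")
  palm_mask(largest_component(bits))
}

#' Band-pass vein enhancement
#'
#' Convolves with the difference of two Gaussians (narrow minus wide, scale
#' ratio `cfg$dog_ratio`) in signed real arithmetic with reflective padding,
#' then affinely rescales the response to `[0, 255]` using the min/max over
#' mask pixels. Background pixels are set to 0; a flat response maps to 128.
#'
#' @inheritParams segment_palm
#' @param mask a [palm_mask].
#' @return enhanced grayscale matrix.
#' @export
dog_enhance <- function(img, mask, cfg = preprocess_config()) {
  img <- check_image(img)
  resp <- dog_response(img, cfg$dog_sigma, cfg$dog_ratio)
  out <- matrix(0, nrow(img), ncol(img))
  rng <- range(resp[mask$bits])
  if (diff(rng) < 1e-12) {
    out[mask$bits] <- 128
  } else {
    out[mask$bits] <- round(255 * (resp[mask$bits] - rng[1]) / diff(rng))
  }
  out
}

#' Histogram equalization over the palm region
#'
#' Applies the monotone map `round(255 * CDF)` built from the intensity
#' distribution inside the mask (or the whole frame when
#' `cfg$he_scope = "full_frame"`). The relative intensity order of mask
#' pixels is preserved; background stays 0.
#'
#' @inheritParams dog_enhance
#' @return equalized grayscale matrix.
#' @export
equalize <- function(img, mask, cfg = preprocess_config()) {
  img <- check_image(img)
  if (mask$area == 0) abort("empty mask: nothing to equalize")
  scope <- if (cfg$he_scope == "mask_only") mask$bits else
    matrix(TRUE, nrow(img), ncol(img))
  vals <- round(img[scope])
  h <- tabulate(vals + 1L, nbins = 256L)
  map <- round(255 * cumsum(h) / sum(h))
  out <- matrix(0, nrow(img), ncol(img))
  out[mask$bits] <- map[round(img[mask$bits]) + 1L]
  out
}

#' Full preprocessing pipeline
#'
#' `segment_palm` -> `crop_wrist` -> `dog_enhance` -> `equalize`, in that
#' order. The pipeline is deliberately not idempotent: equalizing an already
#' equalized image changes it again.
#'
#' @inheritParams segment_palm
#' @return list with `image` (enhanced matrix, background 0) and `mask`
#'   (the wrist-cropped [palm_mask]).
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  img <- check_image(img, min_dim = 64L)
  mask <- segment_palm(img, cfg)
  mask <- crop_wrist(mask, cfg$crop_factor)
  enh <- dog_enhance(img, mask, cfg)
  enh <- equalize(enh, mask, cfg)
  list(image = enh, mask = mask)
}
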