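#' Binary palm masks
#'
#' A `palm_mask` is a logical matrix of foreground bits together with the
#' centroid (mean 0-based `(row, col)` of the set bits) and the foreground
#' area in pixels. After finalization the foreground is a single connected
#' component.
#'
#' @param bits logical (or 0/1 numeric) matrix.
#' @return object of class `palm_mask` with fields `bits`, `centroid`
#'   (`c(row, col)`, 0-based), `area`.
#' @export
palm_mask <- function(bits) {
  if (is.numeric(bits)) bits <- bits != 0
  stopifnot(is.matrix(bits), is.logical(bits))
  idx <- which(bits, arr.ind = TRUE)
  centroid <- if (nrow(idx)) c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1) else c(NA_real_, NA_real_)
  structure(
    list(bits = bits, centroid = unname(centroid), area = nrow(idx)),
    class = "palm_mask"
  )
}

#' @export
print.palm_mask <- function(x, ...) {
  cat(sprintf(
    "<palm_mask> %dx%d, area %d px, centroid (row=%.1f, col=%.1f)\n",
    nrow(x$bits), ncol(x$bits), x$area, x$centroid[1], x$centroid[2]
  ))
  invisible(x)
}

# keep only the largest 8-connected foreground component
largest_component <- function(bits) {
  if (!any(bits)) return(bits)
  lab <- EBImage::bwlabel(bits * 1)
  tab <- tabulate(lab[lab > 0])
  bits & (lab == which.max(tab))
}

fill_holes <- function(bits) {
  if (!any(bits)) return(bits)
  EBImage::imageData(EBImage::fillHull(EBImage::Image(bits * 1))) != 0
}

# effective radius of a disk with the mask's area; the unit of normalized
# centroid-relative coordinates
mask_radius <- function(mask) sqrt(mask$area / pi)

#' Erode a palm mask by a disc of the given radius
#'
#' Used to restrict keypoints to the palm interior, away from the
#' segmentation boundary. Radius 0 returns the mask unchanged; if erosion
#' would empty the mask, the original is returned.
#'
#' @param mask a [palm_mask].
#' @param radius_px disc radius in pixels.
#' @return a [palm_mask].
#' @export
erode_palm_mask <- function(mask, radius_px) {
  if (radius_px <= 0 || mask$area == 0) return(mask)
  bits <- EBImage::imageData(EBImage::erode(
    EBImage::Image(mask$bits * 1),
    EBImage::makeBrush(2 * as.integer(radius_px) + 1, "disc")
  )) != 0
  if (!any(bits)) return(mask)
  palm_mask(bits)
}

#' Trace the mask outline
#'
#' @param mask a [palm_mask].
#' @return two-column matrix of 0-based `(row, col)` boundary vertices of the
#'   largest foreground component (a closed polygon).
#' @export
mask_outline <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask$bits * 1))
  poly <- oc[[which.max(vapply(oc, nrow, 1L))]]
  # EBImage returns (x, y) 0-based in its column-major frame: x = row here
  cbind(row = poly[, 1], col = poly[, 2])
}
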