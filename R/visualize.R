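#' Side-by-side match visualization
#'
#' Renders the two images next to each other and draws one line per
#' candidate match, color-coded by filtering outcome: green for kept pairs,
#' blue for pairs removed by the neighbor-based layer, red for pairs
#' removed by the LBP-based layer.
#'
#' @param matches a `filtered_matches` (or `match_set`) tibble.
#' @param img_a,img_b grayscale matrices in `[0, 255]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_match_overlay <- function(matches, img_a, img_b, path) {
  img_a <- check_image(img_a); img_b <- check_image(img_b)
  m <- as_filtered_matches(matches)
  h <- max(nrow(img_a), nrow(img_b))
  w <- ncol(img_a) + ncol(img_b)
  canvas <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    canvas[seq_len(nrow(img_a)), seq_len(ncol(img_a)), ch] <- img_a / 255
    canvas[seq_len(nrow(img_b)), ncol(img_a) + seq_len(ncol(img_b)), ch] <- img_b / 255
  }
  cols <- list(kept = c(0, 1, 0), removed_neighbor = c(0, 0.4, 1),
               removed_lbp = c(1, 0, 0))
  off <- ncol(img_a)
  for (i in seq_len(nrow(m))) {
    col <- cols[[m$label[i]]] %||% c(1, 1, 0)
    x1 <- m$x_a[i]; y1 <- m$y_a[i]
    x2 <- m$x_b[i] + off; y2 <- m$y_b[i]
    len <- max(2, ceiling(2 * sqrt((x2 - x1)^2 + (y2 - y1)^2)))
    t <- seq(0, 1, length.out = len)
    rr <- pmin(pmax(round(y1 + t * (y2 - y1)) + 1, 1), h)
    cc <- pmin(pmax(round(x1 + t * (x2 - x1)) + 1, 1), w)
    for (ch in 1:3) canvas[cbind(rr, cc, ch)] <- col[ch]
  }
  png::writePNG(canvas, path)
  invisible(path)
}
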