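#' Grayscale image containers and input/output
#'
#' Throughout the package a grayscale image is an ordinary numeric matrix with
#' intensities in `[0, 255]`, row-major with the origin at the top-left corner.
#' Pixel coordinates are 0-based: a keypoint at `(x, y)` sits at matrix cell
#' `[y + 1, x + 1]` (`x` = column, `y` = row).
#'
#' @param x object to coerce / validate.
#' @return `as_gray_image()` returns a numeric matrix with intensities clamped
#'   to `[0, 255]`.
#' @name gray-image
NULL

#' @rdname gray-image
#' @export
as_gray_image <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("a grayscale image must be a numeric matrix")
  }
  if (anyNA(x)) abort("image contains NA intensities")
  # values in [0,1] are accepted as normalized and promoted to 8-bit range
  if (max(x) <= 1 && min(x) >= 0 && max(x) > 0) x <- x * 255
  pmin(pmax(x, 0), 255)
}

check_image <- function(img, min_dim = 1L) {
  img <- as_gray_image(img)
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    abort(sprintf("image must be at least %dx%d", min_dim, min_dim))
  }
  img
}

#' Read a grayscale image
#'
#' Reads PNG (via the \pkg{png} package), PGM (P2/P5, parsed directly) or
#' JPEG/TIFF (via \pkg{EBImage}). Color inputs are converted to luminance
#' (Rec. 601 weights) before processing.
#'
#' @param path path to an image file.
#' @return numeric matrix with intensities in `[0, 255]`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    return(luminance(a) * 255)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pgm(path))
  if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x (columns) in the first dimension
    if (length(dim(a)) == 3) a <- apply(a, c(1, 2), function(v) sum(v * c(0.299, 0.587, 0.114)[seq_along(v)]))
    return(t(a) * 255)
  }
  abort(sprintf("unsupported image format: '%s'", ext))
}

luminance <- function(a) {
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) {
      a[, , 1] * 0.299 + a[, , 2] * 0.587 + a[, , 3] * 0.114
    } else {
      a[, , 1]
    }
  } else {
    a
  }
}

#' Write a grayscale image or mask as PNG
#'
#' Masks are written with the 0/255 convention.
#'
#' @param img numeric matrix in `[0, 255]`, or a logical matrix / [palm_mask].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  if (inherits(img, "palm_mask")) img <- img$bits
  if (is.logical(img)) img <- img * 255
  img <- as_gray_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

# Minimal PGM (P2 ascii / P5 binary) reader; the format is three header tokens
# (magic, width height, maxval) followed by pixels.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) abort("not a PGM file (expected P2 or P5)")
  tokens <- character(0)
  buf <- character(0)
  # read header tokens, skipping '#' comments
  while (length(tokens) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) abort("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); maxval <- as.integer(tokens[3])
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m * (255 / maxval)
}

#' @rdname read_gray
#' @param img numeric matrix in `[0, 255]`.
#' @export
write_pgm <- function(img, path) {
  img <- round(as_gray_image(img))
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(img, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
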