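#' Synthetic NIR palm-vein image generation
#'
#' Seeded generators for hand-shaped test images: a bright palm (with five
#' finger lobes and a forearm stub for wrist-crop testing) on a dark
#' background, carrying a random branching tree of dark curvilinear veins.
#' Samples of one identity share the vein tree; acquisitions differ by
#' rotation / scale / translation / perspective, uneven illumination, blur
#' and noise — mimicking contact-free NIR capture. Every artifact is a pure
#' function of its seeds, and each rendered sample returns its exact
#' ground-truth homography so correspondences can be checked exactly.
#'
#' @name synthetic-veins
NULL

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% 2147483647)
  force(code)
}

#' Generate a synthetic identity
#'
#' Draws a hand silhouette (palm ellipse, five finger capsules, forearm
#' stub) and grows a branching vein tree inside it by seeded random walks
#' from 2-4 roots near the wrist. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param size canvas side in pixels (square frame).
#' @return object of class `identity_spec`: `seed`, `size`, `shape`
#'   (silhouette parameters), `tree` (list of branches, each with a
#'   `points` matrix of 0-based `(x, y)` control points and a `width`),
#'   `hand_outline` (closed polygon from [mask_outline()]), and `mask`
#'   (the canonical silhouette as a [palm_mask]).
#' @export
generate_identity <- function(seed, size = 256L) {
  with_seed(seed, {
    # hand geometry varies between identities, as real hands do; samples of
    # one identity share it exactly
    cx <- size / 2 + runif(1, -6, 6)        # palm center, x = col
    cy <- size * 0.47 + runif(1, -5, 5)     # y = row; high so the forearm
    pa <- size * 0.18 * runif(1, 0.88, 1.12) # stub below stays long
    pb <- size * 0.19 * runif(1, 0.88, 1.12)
    ang <- c(-50, -26, -2, 22, 48) + runif(5, -8, 8)     # finger directions
    len <- size * c(0.16, 0.21, 0.23, 0.21, 0.14) * runif(5, 0.85, 1.15)
    fw <- size * c(0.030, 0.033, 0.033, 0.031, 0.028) * runif(5, 0.85, 1.15)
    shape <- list(cx = cx, cy = cy, pa = pa, pb = pb,
                  finger_angle = ang, finger_len = len, finger_width = fw,
                  stub_width = size * runif(1, 0.045, 0.06),
                  base = round(runif(1, 165, 180)))
    mask_bits <- hand_mask_bits(shape, size)
    tree <- grow_vein_tree(shape, mask_bits, size)
    mask <- palm_mask(mask_bits)
    structure(
      list(seed = seed, size = size, shape = shape, tree = tree,
           hand_outline = mask_outline(mask), mask = mask),
      class = "identity_spec"
    )
  })
}

# rasterize the silhouette: palm ellipse + finger capsules + forearm stub
hand_mask_bits <- function(shape, size) {
  x <- matrix(rep(0:(size - 1), each = size), size) # col index
  y <- matrix(rep(0:(size - 1), times = size), size) # row index
  inside <- ((x - shape$cx) / shape$pa)^2 + ((y - shape$cy) / shape$pb)^2 <= 1
  for (f in seq_along(shape$finger_angle)) {
    th <- shape$finger_angle[f] * pi / 180
    dx <- sin(th); dy <- -cos(th)
    bx <- shape$cx + dx * shape$pa * 0.8
    by <- shape$cy + dy * shape$pb * 0.8
    ex <- bx + dx * shape$finger_len[f]
    ey <- by + dy * shape$finger_len[f]
    inside <- inside | capsule_dist2(x, y, bx, by, ex, ey) <= shape$finger_width[f]^2
  }
  # forearm stub down to the frame edge
  inside <- inside | (abs(x - shape$cx) <= shape$stub_width &
                        y >= shape$cy + shape$pb * 0.6)
  inside
}

# squared distance from grid points to the segment (x1,y1)-(x2,y2)
capsule_dist2 <- function(x, y, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((x - x1) * vx + (y - y1) * vy) / L2, 0), 1)
  (x - (x1 + t * vx))^2 + (y - (y1 + t * vy))^2
}

grow_vein_tree <- function(shape, mask_bits, size) {
  n_roots <- sample(3:5, 1)
  branches <- list()
  queue <- lapply(seq_len(n_roots), function(i) {
    repeat {
      x <- shape$cx + runif(1, -0.7, 0.7) * shape$pa
      y <- shape$cy + shape$pb * runif(1, 0.5, 0.8)
      if (mask_bits[round(y) + 1, round(x) + 1]) break
    }
    list(
      x = x, y = y,
      dir = -pi / 2 + runif(1, -0.7, 0.7),  # mostly upward
      width = runif(1, 2.2, 3.2), depth = 0
    )
  })
  step <- 4
  inside <- function(x, y) {
    r <- round(y) + 1L; c <- round(x) + 1L
    r >= 1 && r <= size && c >= 1 && c <= size && mask_bits[r, c]
  }
  while (length(queue) && length(branches) < 60) {
    b <- queue[[1]]; queue <- queue[-1]
    pts <- matrix(c(b$x, b$y), ncol = 2)
    dir <- b$dir
    for (k in seq_len(55)) {
      dir <- dir + rnorm(1, 0, 0.3)
      nx <- pts[nrow(pts), 1] + step * cos(dir)
      ny <- pts[nrow(pts), 2] + step * sin(dir)
      if (!inside(nx, ny)) break
      pts <- rbind(pts, c(nx, ny))
      if (runif(1) < 0.22 && b$depth < 4 && length(queue) < 40) {
        queue[[length(queue) + 1]] <- list(
          x = nx, y = ny, dir = dir + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
          width = max(b$width * 0.8, 1.5), depth = b$depth + 1
        )
      }
    }
    if (nrow(pts) >= 3) {
      branches[[length(branches) + 1]] <-
        list(points = unname(pts), width = b$width)
    }
  }
  branches
}

#' Acquisition parameters for one synthetic sample
#'
#' Describes one contact-free capture: geometric pose (rotation in degrees,
#' isotropic scale, translation in pixels, out-of-plane perspective tilt in
#' degrees) and photometric degradation (linear illumination-gradient
#' amplitude as a fraction of intensity, Gaussian blur sigma, additive
#' Gaussian noise sigma in intensity units).
#'
#' @param rotation in-plane rotation, degrees.
#' @param scale isotropic scale in `[0.5, 2]`.
#' @param translation `c(dx, dy)` pixels.
#' @param perspective_tilt forward/backward tilt, degrees.
#' @param illumination_gradient left-right ramp amplitude: the multiplicative
#'   factor runs linearly from `1 - a` at the left edge to `1 + a` at the
#'   right edge.
#' @param blur_sigma,noise_sigma degradation parameters.
#' @param seed seed for the noise stream.
#' @return list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(rotation = 0, scale = 1, translation = c(0, 0),
                             perspective_tilt = 0, illumination_gradient = 0,
                             blur_sigma = 0, noise_sigma = 0, seed = 0L) {
  stopifnot(scale >= 0.5, scale <= 2)
  structure(
    list(rotation = rotation, scale = scale, translation = translation,
         perspective_tilt = perspective_tilt,
         illumination_gradient = illumination_gradient,
         blur_sigma = blur_sigma, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "acquisition_spec"
  )
}

# 3x3 homography for an acquisition, about the frame center, x = col, y = row
acq_homography <- function(acq, size) {
  ctr <- (size - 1) / 2
  Tm <- function(dx, dy) matrix(c(1, 0, 0, 0, 1, 0, dx, dy, 1), 3)
  th <- acq$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  S <- diag(c(acq$scale, acq$scale, 1))
  P <- diag(3)
  P[3, 2] <- tan(acq$perspective_tilt * pi / 180) / (1.2 * size)
  Tm(ctr + acq$translation[1], ctr + acq$translation[2]) %*% P %*% R %*% S %*%
    Tm(-ctr, -ctr)
}

apply_homography <- function(H, xy) {
  p <- H %*% rbind(t(xy), 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

#' Render one synthetic sample
#'
#' Rasterizes the identity's canonical hand (bright region around 165-180,
#' veins darker by a contrast margin, background 10), then applies the
#' acquisition's perspective warp (inverse-mapped, bilinear), multiplicative
#' left-right illumination ramp, Gaussian blur and additive Gaussian noise,
#' in that order. The contrast margin (default 35 pre-blur) is low enough
#' that raw keypoint counts are visibly depressed and recovered by
#' enhancement.
#'
#' @param id an `identity_spec` from [generate_identity()].
#' @param acq an [acquisition_spec()].
#' @param vein_contrast vein darkening in intensity units.
#' @return list: `image` (grayscale matrix), `transform` (3x3 forward
#'   homography mapping canonical 0-based `(x, y)` to sample coordinates),
#'   `acq`.
#' @export
render_sample <- function(id, acq = acquisition_spec(), vein_contrast = 35) {
  size <- id$size
  canon <- render_canonical(id, vein_contrast)
  H <- acq_homography(acq, size)
  img <- warp_image(canon, H, background = 10)
  if (max(img) <= 10 + 1e-9) abort("warp pushed the hand fully out of frame")
  if (acq$illumination_gradient > 0) {
    # left-right multiplicative ramp centered on the hand, reaching factors
    # 1 -/+ (2/3) a at the hand's horizontal extremes (clamped at 1 -/+ a)
    fg <- which(img > 20, arr.ind = TRUE)
    lo <- min(fg[, 2]); hi <- max(fg[, 2])
    dev <- (col(img) - (lo + hi) / 2) / (0.75 * max(hi - lo, 1))
    img <- img * (1 + acq$illumination_gradient * pmin(pmax(dev, -1), 1))
  }
  if (acq$blur_sigma > 0) img <- gaussian_blur(img, acq$blur_sigma)
  if (acq$noise_sigma > 0) {
    img <- img + with_seed(acq$seed, matrix(rnorm(length(img), 0, acq$noise_sigma),
                                            nrow(img)))
  }
  list(image = pmin(pmax(img, 0), 255), transform = H, acq = acq)
}

render_canonical <- function(id, vein_contrast = 35) {
  size <- id$size
  img <- matrix(10, size, size)
  img[id$mask$bits] <- id$shape$base
  # identity-specific skin texture: a smoothed speckle field plus oriented
  # crease-like line segments, as NIR palms show palmprint creases and
  # speckle on top of the vein pattern
  tex <- with_seed(id$seed + 500L, {
    field <- gaussian_blur(matrix(rnorm(size * size), size), 3.5)
    field <- field * (3 / sd(field))
    idx <- which(id$mask$bits, arr.ind = TRUE)
    for (k in seq_len(45)) {
      p <- idx[sample(nrow(idx), 1), ]
      th <- runif(1, 0, pi)
      L <- runif(1, 10, 35)
      amp <- sample(c(-1, 1), 1) * runif(1, 5, 9)
      x1 <- p[2] - 1; y1 <- p[1] - 1
      x2 <- x1 + L * cos(th); y2 <- y1 + L * sin(th)
      rr <- max(1, floor(min(y1, y2) - 4)):min(size, ceiling(max(y1, y2) + 4))
      cc <- max(1, floor(min(x1, x2) - 4)):min(size, ceiling(max(x1, x2) + 4))
      gx <- matrix(rep(cc - 1, each = length(rr)), length(rr))
      gy <- matrix(rep(rr - 1, times = length(cc)), length(rr))
      d2 <- capsule_dist2(gx, gy, x1, y1, x2, y2)
      field[rr, cc] <- field[rr, cc] + amp * exp(-d2 / (2 * 1.3^2))
    }
    field
  })
  img[id$mask$bits] <- img[id$mask$bits] + tex[id$mask$bits]
  dark <- matrix(0, size, size)
  for (b in id$tree) {
    pts <- b$points
    w <- b$width
    for (k in seq_len(nrow(pts) - 1)) {
      x1 <- pts[k, 1]; y1 <- pts[k, 2]; x2 <- pts[k + 1, 1]; y2 <- pts[k + 1, 2]
      rr <- max(1, floor(min(y1, y2) - 3 * w)):min(size, ceiling(max(y1, y2) + 3 * w))
      cc <- max(1, floor(min(x1, x2) - 3 * w)):min(size, ceiling(max(x1, x2) + 3 * w))
      gx <- matrix(rep(cc - 1, each = length(rr)), length(rr))
      gy <- matrix(rep(rr - 1, times = length(cc)), length(rr))
      d2 <- capsule_dist2(gx, gy, x1, y1, x2, y2)
      prof <- vein_contrast * exp(-d2 / (2 * (w / 1.6)^2))
      dark[rr, cc] <- pmax(dark[rr, cc], prof)
    }
  }
  dark[!id$mask$bits] <- 0
  img - dark
}

# inverse-mapped warp with bilinear interpolation
warp_image <- function(img, H, background = 0) {
  size_r <- nrow(img); size_c <- ncol(img)
  Hi <- solve(H)
  xy <- cbind(rep(0:(size_c - 1), each = size_r),
              rep(0:(size_r - 1), times = size_c))
  src <- apply_homography(Hi, xy)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(r, c) {
    ok <- r >= 0 & r <= size_r - 1 & c >= 0 & c <= size_c - 1
    v <- rep(background, length(r))
    v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(y0, x0) +
    fx * (1 - fy) * pick(y0, x0 + 1) +
    (1 - fx) * fy * pick(y0 + 1, x0) +
    fx * fy * pick(y0 + 1, x0 + 1)
  matrix(v, size_r, size_c)
}

#' The six posture archetypes
#'
#' Far from / close to the camera (scale 0.8 / 1.2), in-plane tilt left /
#' right (plus/minus 15 degrees), and forward / backward perspective tilt
#' (plus/minus 10 degrees) — bracketing the rotation and scale grids of the
#' robustness experiments.
#'
#' @return list of 6 parameter lists.
#' @export
posture_archetypes <- function() {
  list(
    far      = list(scale = 0.8),
    close    = list(scale = 1.2),
    tilt_l   = list(rotation = 15),
    tilt_r   = list(rotation = -15),
    pitch_f  = list(perspective_tilt = 10),
    pitch_b  = list(perspective_tilt = -10)
  )
}

#' Generate a labeled synthetic gallery
#'
#' Per identity, samples are drawn (without replacement while they last)
#' from the six posture archetypes, with small seeded jitter in rotation
#' (sd 1.5 deg), scale (sd 0.02) and translation (plus/minus 6 px), a 0.3
#' illumination gradient, 1 px blur and noise sd 4 — the study conditions
#' for all seeded benchmarks. Layout on disk matches the verification
#' module: `dir/<identity>/<sample>.png` plus one `metadata.json` holding
#' every seed and ground-truth transform.
#'
#' @param n_identities,n_samples gallery dimensions (at least 2 each).
#' @param master_seed integer; governs all randomness.
#' @param dir optional output directory; when `NULL` the gallery stays in
#'   memory.
#' @param size canvas side in pixels.
#' @return tibble with one row per sample: `id`, `sample`, `image`
#'   (list-column of matrices), `transform` (list-column of 3x3 forward
#'   homographies), `archetype`, `id_seed`, `acq_seed`. When `dir` is
#'   given the PNGs and `metadata.json` are written there first.
#' @export
generate_gallery <- function(n_identities, n_samples, master_seed = 1L,
                             dir = NULL, size = 256L) {
  stopifnot(n_identities >= 2, n_samples >= 2)
  arche <- posture_archetypes()
  rows <- list()
  for (i in seq_len(n_identities)) {
    id_seed <- (master_seed * 7919 + i * 104729) %% 2147483647
    id <- generate_identity(id_seed, size = size)
    picks <- with_seed(id_seed + 1, {
      if (n_samples <= length(arche)) sample(length(arche), n_samples)
      else c(sample(length(arche)), sample(length(arche), n_samples - length(arche),
                                           replace = TRUE))
    })
    for (j in seq_len(n_samples)) {
      acq_seed <- (id_seed + j * 7211) %% 2147483647
      pars <- arche[[picks[j]]]
      acq <- with_seed(acq_seed, acquisition_spec(
        rotation = (pars$rotation %||% 0) + rnorm(1, 0, 1.5),
        scale = max(0.5, min(2, (pars$scale %||% 1) + rnorm(1, 0, 0.02))),
        translation = runif(2, -6, 6),
        perspective_tilt = pars$perspective_tilt %||% 0,
        illumination_gradient = 0.3,
        blur_sigma = 1, noise_sigma = 4,
        seed = acq_seed
      ))
      smp <- render_sample(id, acq)
      rows[[length(rows) + 1]] <- tibble(
        id = sprintf("id%03d", i),
        sample = sprintf("s%02d", j),
        image = list(smp$image),
        transform = list(smp$transform),
        archetype = names(arche)[picks[j]],
        id_seed = id_seed, acq_seed = acq_seed
      )
    }
  }
  gal <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(nrow(gal))) {
      d <- file.path(dir, gal$id[k])
      dir.create(d, showWarnings = FALSE)
      write_gray(round(gal$image[[k]]), file.path(d, paste0(gal$sample[k], ".png")))
    }
    meta <- list(
      master_seed = master_seed, n_identities = n_identities,
      n_samples = n_samples, size = size,
      samples = lapply(seq_len(nrow(gal)), function(k) {
        list(id = gal$id[k], sample = gal$sample[k],
             id_seed = gal$id_seed[k], acq_seed = gal$acq_seed[k],
             archetype = gal$archetype[k],
             transform = gal$transform[[k]])
      })
    )
    jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  gal
}

#' Ground-truth correspondence between two samples of one identity
#'
#' Composes the two forward homographies into the map taking sample-A
#' coordinates to sample-B coordinates.
#'
#' @param transform_a,transform_b 3x3 forward transforms of the samples.
#' @return 3x3 homography.
#' @export
pair_transform <- function(transform_a, transform_b) {
  transform_b %*% solve(transform_a)
}
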