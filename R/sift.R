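#' Scale-invariant keypoint detection and description
#'
#' A self-contained SIFT implementation following Lowe's five steps:
#' (1) scale-space extrema detection in a difference-of-Gaussians pyramid,
#' (2) keypoint localization by quadratic interpolation with contrast and
#' edge-response rejection, (3) orientation assignment from a smoothed
#' 36-bin gradient histogram, (4) generation of 4x4x8 gradient-orientation
#' descriptors, and (5) emission of 128-dimensional nonnegative vectors
#' (unit Euclidean norm after the standard 0.2 clipping).
#'
#' Keypoints whose `(x, y)` location falls outside the supplied mask are
#' discarded. An image without extrema yields an empty set, not an error.
#'
#' @param img grayscale matrix in `[0, 255]` (typically the output of
#'   [preprocess()]).
#' @param mask optional [palm_mask] restricting keypoint locations.
#' @param n_features keep at most this many keypoints, strongest
#'   (largest absolute DoG response) first. `Inf` keeps all.
#' @param n_octave_layers scales per octave (Lowe's `s`).
#' @param sigma0 base blur of each octave in pixels.
#' @param contrast_threshold minimum interpolated |DoG| response
#'   (on intensities scaled to `[0, 1]`), divided by `n_octave_layers`.
#' @param edge_threshold principal-curvature ratio limit.
#' @return a `descriptor_set`: list with `keypoints`
#'   (tibble: `x`, `y`, `scale`, `orientation`, `response`) and `vectors`
#'   (N x 128 matrix, rows unit-norm). Coordinates are 0-based,
#'   `x` = column, `y` = row.
#' @export
detect_sift <- function(img, mask = NULL, n_features = 500,
                        n_octave_layers = 3, sigma0 = 1.6,
                        contrast_threshold = 0.04, edge_threshold = 10) {
  img <- check_image(img)
  base <- img / 255
  nl <- n_octave_layers
  n_oct <- max(1L, floor(log2(min(dim(base)) / 16)) + 1L)

  pyr <- sift_pyramid(base, n_oct, nl, sigma0)
  cand <- sift_extrema(pyr$dog, nl, contrast_threshold)
  kp <- sift_localize(pyr$dog, cand, nl, sigma0, contrast_threshold, edge_threshold)

  if (nrow(kp)) {
    inb <- kp$x >= 0 & kp$x <= ncol(img) - 1 & kp$y >= 0 & kp$y <= nrow(img) - 1
    kp <- kp[inb, , drop = FALSE]
  }
  if (!is.null(mask) && nrow(kp)) {
    keep <- mask$bits[cbind(pmin(round(kp$y), nrow(img) - 1) + 1L,
                            pmin(round(kp$x), ncol(img) - 1) + 1L)]
    kp <- kp[keep, , drop = FALSE]
  }
  if (nrow(kp) > n_features) {
    kp <- kp[order(-abs(kp$response)), , drop = FALSE][seq_len(n_features), , drop = FALSE]
  }
  if (!nrow(kp)) return(empty_descriptor_set())

  oriented <- sift_orientations(pyr$gauss, kp, nl)
  if (!nrow(oriented)) return(empty_descriptor_set())
  vec <- sift_descriptors(pyr$gauss, oriented, nl)
  descriptor_set(
    tibble(
      x = unname(oriented$x), y = unname(oriented$y),
      scale = unname(oriented$scale),
      orientation = unname(oriented$orientation),
      response = unname(oriented$response)
    ),
    vec
  )
}

descriptor_set <- function(keypoints, vectors) {
  stopifnot(nrow(keypoints) == nrow(vectors), ncol(vectors) == 128)
  structure(list(keypoints = keypoints, vectors = vectors),
            class = "descriptor_set")
}

empty_descriptor_set <- function() {
  descriptor_set(
    tibble(x = double(), y = double(), scale = double(),
           orientation = double(), response = double()),
    matrix(0, 0, 128)
  )
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d keypoints x 128\n", nrow(x$vectors)))
  invisible(x)
}

#' @export
length.descriptor_set <- function(x) nrow(x$vectors)

subset_descriptor_set <- function(d, idx) {
  descriptor_set(d$keypoints[idx, , drop = FALSE], d$vectors[idx, , drop = FALSE])
}

# ---- pyramid -------------------------------------------------------------

sift_pyramid <- function(base, n_oct, nl, sigma0) {
  k <- 2^(1 / nl)
  sig_abs <- sigma0 * k^(0:(nl + 2))
  # incremental blurs between consecutive layers
  sig_inc <- sqrt(diff(sig_abs^2))
  gauss <- vector("list", n_oct)
  dog <- vector("list", n_oct)
  first <- gaussian_blur(base, sqrt(max(sigma0^2 - 0.25, 0.01)))
  for (o in seq_len(n_oct)) {
    g <- vector("list", nl + 3)
    g[[1]] <- first
    for (i in 2:(nl + 3)) g[[i]] <- gaussian_blur(g[[i - 1]], sig_inc[i - 1])
    gauss[[o]] <- g
    dog[[o]] <- lapply(seq_len(nl + 2), function(i) g[[i + 1]] - g[[i]])
    if (o < n_oct) {
      dn <- g[[nl + 1]] # blur 2*sigma0 -> sigma0 after halving
      first <- dn[seq(1, nrow(dn), by = 2), seq(1, ncol(dn), by = 2), drop = FALSE]
    }
  }
  list(gauss = gauss, dog = dog)
}

nb_max3 <- function(M) {
  n <- nrow(M); m <- ncol(M)
  P <- matrix(-Inf, n + 2, m + 2)
  P[2:(n + 1), 2:(m + 1)] <- M
  pmax(P[1:n, 1:m], P[1:n, 2:(m + 1)], P[1:n, 3:(m + 2)],
       P[2:(n + 1), 1:m], P[2:(n + 1), 2:(m + 1)], P[2:(n + 1), 3:(m + 2)],
       P[3:(n + 2), 1:m], P[3:(n + 2), 2:(m + 1)], P[3:(n + 2), 3:(m + 2)])
}

nb_min3 <- function(M) -nb_max3(-M)

# candidate extrema: tibble(octave, layer, r, c) with 1-based matrix indices
sift_extrema <- function(dog, nl, contrast_threshold) {
  pre <- 0.5 * contrast_threshold / nl
  out <- list()
  for (o in seq_along(dog)) {
    d <- dog[[o]]
    nr <- nrow(d[[1]]); nc <- ncol(d[[1]])
    if (nr < 12 || nc < 12) next
    border <- matrix(FALSE, nr, nc)
    border[5:(nr - 4), 5:(nc - 4)] <- TRUE
    for (i in 2:(nl + 1)) {
      D <- d[[i]]
      ismax <- D >= nb_max3(d[[i - 1]]) & D >= nb_max3(d[[i + 1]]) &
        D == nb_max3(D) & D > pre
      ismin <- D <= nb_min3(d[[i - 1]]) & D <= nb_min3(d[[i + 1]]) &
        D == nb_min3(D) & D < -pre
      hit <- which((ismax | ismin) & border, arr.ind = TRUE)
      if (nrow(hit)) {
        out[[length(out) + 1]] <- tibble(
          octave = o, layer = i, r = hit[, 1], c = hit[, 2]
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(octave = integer(), layer = integer(),
                  r = integer(), c = integer()))
  }
  dplyr::bind_rows(out)
}

# quadratic localization; returns tibble(x, y, scale, response, octave, layer,
# r, c, ds) with base-image 0-based coordinates
sift_localize <- function(dog, cand, nl, sigma0, contrast_threshold,
                          edge_threshold) {
  empty <- tibble(x = double(), y = double(), scale = double(),
                  response = double(), octave = integer(), layer = integer(),
                  r = integer(), c = integer(), ds = double())
  if (!nrow(cand)) return(empty)
  res <- list()
  for (o in unique(cand$octave)) {
    sub <- cand[cand$octave == o, ]
    d <- dog[[o]]
    nr <- nrow(d[[1]]); nc <- ncol(d[[1]])
    for (i in unique(sub$layer)) {
      s2 <- sub[sub$layer == i, ]
      D1 <- d[[i - 1]]; D2 <- d[[i]]; D3 <- d[[i + 1]]
      r <- s2$r; c <- s2$c
      ox <- oy <- os <- rep(0, length(r))
      for (pass in 1:3) {
        ii <- cbind(r, c)
        v <- D2[ii]
        dx <- (D2[cbind(r, c + 1)] - D2[cbind(r, c - 1)]) / 2
        dy <- (D2[cbind(r + 1, c)] - D2[cbind(r - 1, c)]) / 2
        ds <- (D3[ii] - D1[ii]) / 2
        dxx <- D2[cbind(r, c + 1)] + D2[cbind(r, c - 1)] - 2 * v
        dyy <- D2[cbind(r + 1, c)] + D2[cbind(r - 1, c)] - 2 * v
        dss <- D3[ii] + D1[ii] - 2 * v
        dxy <- (D2[cbind(r + 1, c + 1)] - D2[cbind(r + 1, c - 1)] -
                  D2[cbind(r - 1, c + 1)] + D2[cbind(r - 1, c - 1)]) / 4
        dxs <- (D3[cbind(r, c + 1)] - D3[cbind(r, c - 1)] -
                  D1[cbind(r, c + 1)] + D1[cbind(r, c - 1)]) / 4
        dys <- (D3[cbind(r + 1, c)] - D3[cbind(r - 1, c)] -
                  D1[cbind(r + 1, c)] + D1[cbind(r - 1, c)]) / 4
        # solve H * off = -g by adjugate, vectorized
        det <- dxx * (dyy * dss - dys^2) - dxy * (dxy * dss - dys * dxs) +
          dxs * (dxy * dys - dyy * dxs)
        det[abs(det) < 1e-30] <- NA
        a11 <- dyy * dss - dys^2; a12 <- dxs * dys - dxy * dss
        a13 <- dxy * dys - dxs * dyy
        a22 <- dxx * dss - dxs^2; a23 <- dxy * dxs - dxx * dys
        a33 <- dxx * dyy - dxy^2
        ox <- -(a11 * dx + a12 * dy + a13 * ds) / det
        oy <- -(a12 * dx + a22 * dy + a23 * ds) / det
        os <- -(a13 * dx + a23 * dy + a33 * ds) / det
        ox[is.na(ox)] <- 99; oy[is.na(oy)] <- 99; os[is.na(os)] <- 99
        moved <- abs(ox) > 0.5 | abs(oy) > 0.5
        if (pass == 3 || !any(moved)) break
        # shift integer position toward the interpolated optimum and retry
        c <- pmin(pmax(c + ifelse(abs(ox) > 0.5, sign(ox), 0), 5), nc - 4)
        r <- pmin(pmax(r + ifelse(abs(oy) > 0.5, sign(oy), 0), 5), nr - 4)
      }
      val <- D2[cbind(r, c)] + 0.5 * (dx * ox + dy * oy + ds * os)
      tr <- dxx + dyy
      det2 <- dxx * dyy - dxy^2
      et <- edge_threshold
      keep <- abs(ox) <= 0.6 & abs(oy) <= 0.6 & abs(os) <= 0.6 &
        abs(val) >= contrast_threshold / nl &
        det2 > 0 & tr^2 / det2 < (et + 1)^2 / et
      if (!any(keep)) next
      step <- 2^(o - 1)
      res[[length(res) + 1]] <- tibble(
        x = (c[keep] - 1 + ox[keep]) * step,
        y = (r[keep] - 1 + oy[keep]) * step,
        scale = sigma0 * 2^((i - 1 + os[keep]) / nl) * step,
        response = val[keep],
        octave = o, layer = i, r = r[keep], c = c[keep], ds = os[keep]
      )
    }
  }
  if (!length(res)) return(empty)
  out <- dplyr::bind_rows(res)
  # deduplicate extrema localized to the same cell
  out[!duplicated(out[, c("octave", "layer", "r", "c")]), , drop = FALSE]
}

# ---- orientation ----------------------------------------------------------

layer_gradient <- function(G) {
  nr <- nrow(G); nc <- ncol(G)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (G[, 3:nc] - G[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (G[3:nr, ] - G[1:(nr - 2), ]) / 2
  list(mag = sqrt(gx^2 + gy^2), ang = atan2(gy, gx))
}

# expand keypoints with one row per dominant orientation (up to 2 peaks)
sift_orientations <- function(gauss, kp, nl) {
  grads <- new.env(parent = emptyenv())
  get_grad <- function(o, i) {
    key <- paste(o, i)
    if (is.null(grads[[key]])) grads[[key]] <- layer_gradient(gauss[[o]][[i]])
    grads[[key]]
  }
  rows <- vector("list", nrow(kp))
  for (j in seq_len(nrow(kp))) {
    o <- kp$octave[j]; i <- kp$layer[j]
    g <- get_grad(o, i)
    nr <- nrow(g$mag); nc <- ncol(g$mag)
    sig_oct <- kp$scale[j] / 2^(o - 1)
    radius <- max(2L, round(4.5 * sig_oct))
    r0 <- kp$r[j]; c0 <- kp$c[j]
    rr <- max(2, r0 - radius):min(nr - 1, r0 + radius)
    cc <- max(2, c0 - radius):min(nc - 1, c0 + radius)
    m <- g$mag[rr, cc]; a <- g$ang[rr, cc]
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    w <- as.vector(m * exp(-d2 / (2 * (1.5 * sig_oct)^2)))
    b <- (floor(as.vector(a) / (2 * pi / 36)) %% 36) + 1
    h <- numeric(36)
    agg <- rowsum(w, b)
    h[as.integer(rownames(agg))] <- agg[, 1]
    # circular smoothing with [1 4 6 4 1] / 16
    sm <- function(v) {
      (v[c(35:36, 1:34)] + v[c(3:36, 1:2)] +
         4 * (v[c(36, 1:35)] + v[c(2:36, 1)]) + 6 * v) / 16
    }
    h <- sm(sm(h))
    mx <- max(h)
    if (mx <= 0) next
    left <- h[c(36, 1:35)]; right <- h[c(2:36, 1)]
    peaks <- which(h >= 0.8 * mx & h > left & h >= right)
    if (!length(peaks)) peaks <- which.max(h)
    peaks <- peaks[order(-h[peaks])][seq_len(min(2, length(peaks)))]
    den <- h[peaks] * 2 - left[peaks] - right[peaks] # = h_l - 2h + h_r negated
    off <- ifelse(abs(den) < 1e-12, 0, 0.5 * (left[peaks] - right[peaks]) / -den)
    theta <- ((peaks - 1 + 0.5 + off) * (2 * pi / 36)) %% (2 * pi)
    rows[[j]] <- tibble(
      x = kp$x[j], y = kp$y[j], scale = kp$scale[j],
      orientation = theta, response = kp$response[j],
      octave = o, layer = i, r = r0, c = c0
    )
  }
  dplyr::bind_rows(rows)
}

# ---- descriptor -----------------------------------------------------------

sift_descriptors <- function(gauss, kp, nl, d = 4L, nbins = 8L) {
  grads <- new.env(parent = emptyenv())
  get_grad <- function(o, i) {
    key <- paste(o, i)
    if (is.null(grads[[key]])) grads[[key]] <- layer_gradient(gauss[[o]][[i]])
    grads[[key]]
  }
  out <- matrix(0, nrow(kp), d * d * nbins)
  for (j in seq_len(nrow(kp))) {
    o <- kp$octave[j]; i <- kp$layer[j]
    g <- get_grad(o, i)
    nr <- nrow(g$mag); nc <- ncol(g$mag)
    sig_oct <- kp$scale[j] / 2^(o - 1)
    theta <- kp$orientation[j]
    hist_width <- 3 * sig_oct
    radius <- min(round(hist_width * sqrt(2) * (d + 1) * 0.5 + 0.5),
                  ceiling(sqrt(nr^2 + nc^2)))
    r0 <- kp$r[j]; c0 <- kp$c[j]
    rr <- max(2, r0 - radius):min(nr - 1, r0 + radius)
    cc <- max(2, c0 - radius):min(nc - 1, c0 + radius)
    di <- rep(rr - r0, times = length(cc))
    dj <- rep(cc - c0, each = length(rr))
    # rotate sample offsets by -theta into the keypoint's local frame
    ct <- cos(theta) / hist_width; st <- sin(theta) / hist_width
    c_rot <- dj * ct + di * st
    r_rot <- di * ct - dj * st
    rbin <- r_rot + d / 2 - 0.5
    cbin <- c_rot + d / 2 - 0.5
    ok <- rbin > -1 & rbin < d & cbin > -1 & cbin < d
    if (!any(ok)) next
    m <- g$mag[rr, cc][ok]; a <- g$ang[rr, cc][ok]
    rbin <- rbin[ok]; cbin <- cbin[ok]
    w <- m * exp(-(c_rot[ok]^2 + r_rot[ok]^2) / (0.5 * d * d))
    obin <- ((a - theta) / (2 * pi / nbins)) %% nbins
    rf <- floor(rbin); cf <- floor(cbin); of <- floor(obin)
    fr <- rbin - rf; fc <- cbin - cf; fo <- obin - of
    acc <- numeric((d + 2) * (d + 2) * nbins)
    for (dr in 0:1) for (dc in 0:1) for (dd in 0:1) {
      ww <- w * (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc) *
        (if (dd) fo else 1 - fo)
      rI <- rf + 1 + dr          # 0 .. d+1
      cI <- cf + 1 + dc
      oI <- (of + dd) %% nbins   # circular orientation
      lin <- (rI * (d + 2) + cI) * nbins + oI + 1
      agg <- rowsum(ww, lin)
      ids <- as.integer(rownames(agg))
      acc[ids] <- acc[ids] + agg[, 1]
    }
    arr <- array(acc, dim = c(nbins, d + 2, d + 2)) # [o, c, r]
    v <- as.vector(aperm(arr[, 2:(d + 1), 2:(d + 1)], c(1, 2, 3)))
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-12) next
    v <- pmin(v / nrm, 0.2)
    v <- v / sqrt(sum(v^2))
    out[j, ] <- v
  }
  out
}
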