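# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# exhaustive Otsu: try all 256 thresholds, classes <= t / > t, compute the
# between-class variance directly from pixel values, smallest maximizer
oracle_otsu <- function(img) {
  vals <- round(as.vector(img))
  n <- length(vals)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    a <- vals[vals <= t]; b <- vals[vals > t]
    if (!length(a) || !length(b)) next
    v <- (length(a) / n) * (length(b) / n) * (mean(a) - mean(b))^2
    if (v > best_v + 1e-12) {
      best_v <- v; best_t <- t
    }
  }
  best_t
}

# 4/8-connected component labeling by BFS (queue on a preallocated stack)
oracle_components <- function(bits) {
  lab <- matrix(0L, nrow(bits), ncol(bits))
  cur <- 0L
  nr <- nrow(bits); nc <- ncol(bits)
  for (s in which(bits)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (bits[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

# continuous 2-D Gaussian of Eq.-1 form
oracle_gauss2 <- function(x, y, sigma) {
  exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
}

# random nonnegative descriptor set with unit-L2 rows (plain-SIFT-like)
random_descriptor_set <- function(n, seed, sparsity = 0.5) {
  set.seed(seed)
  v <- matrix(runif(n * 128), n) * (matrix(runif(n * 128), n) > sparsity)
  v[rowSums(v) == 0, 1] <- 1
  vn <- v / sqrt(rowSums(v^2))
  palmvein:::descriptor_set(
    tibble::tibble(x = runif(n, 10, 100), y = runif(n, 10, 100),
                   scale = rep(2, n), orientation = rep(0, n),
                   response = rep(0.1, n)),
    vn
  )
}

# raw (not unit-normalized) nonnegative descriptor matrix
random_raw_descriptors <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * 128), n) * (matrix(runif(n * 128), n) > 0.4)
}

disk_mask <- function(size, center_rc, radius) {
  d2 <- (row(matrix(0, size, size)) - 1 - center_rc[1])^2 +
    (col(matrix(0, size, size)) - 1 - center_rc[2])^2
  palm_mask(d2 <= radius^2)
}
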