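#' RootSIFT descriptor transform
#'
#' Maps each raw descriptor row `v` to `sqrt(v / sum(v))` (L1-normalize,
#' then elementwise square root), so that Euclidean distance between
#' transformed rows equals the Hellinger-kernel distance between the
#' L1-normalized originals:
#' \deqn{\|\hat x - \hat y\|^2 = 2 - 2 \sum_i \sqrt{x_i y_i}.}
#' Output rows have unit Euclidean norm. Rows with zero L1 mass carry no
#' gradient information and are dropped together with their keypoints
#' (with a message, not an error).
#'
#' @param d a `descriptor_set` with nonnegative entries.
#' @return a `descriptor_set` with unit-norm rows and attribute
#'   `root_transformed = TRUE`.
#' @export
root_sift <- function(d) {
  stopifnot(inherits(d, "descriptor_set"))
  v <- d$vectors
  if (any(v < 0)) abort("descriptors must be nonnegative")
  if (!nrow(v)) {
    out <- d
    attr(out, "root_transformed") <- TRUE
    return(out)
  }
  s <- rowSums(v)
  drop <- s == 0
  if (any(drop)) {
    message(sprintf("root_sift: dropping %d zero-mass descriptor row(s)", sum(drop)))
    v <- v[!drop, , drop = FALSE]
    s <- s[!drop]
    d <- subset_descriptor_set(d, !drop)
  }
  out <- descriptor_set(d$keypoints, sqrt(v / s))
  attr(out, "root_transformed") <- TRUE
  out
}

#' Hellinger kernel of two L1-normalized nonnegative vectors
#'
#' \deqn{H(x, y) = \sum_i \sqrt{x_i y_i}} for nonnegative `x`, `y` with unit
#' L1 norm (checked to 1e-8). Symmetric, `H(x, x) = 1`, 0 for vectors with
#' disjoint support.
#'
#' @param x,y nonnegative numeric vectors of equal length summing to 1.
#' @return similarity in `[0, 1]`.
#' @export
hellinger <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("hellinger requires nonnegative inputs")
  if (abs(sum(x) - 1) > 1e-8 || abs(sum(y) - 1) > 1e-8) {
    abort("hellinger requires unit L1 norm (tolerance 1e-8)")
  }
  sum(sqrt(x * y))
}

#' Match parameters
#'
#' @param dist_ratio Lowe ratio-test threshold in `(0, 1]`: a query
#'   descriptor matches its nearest gallery descriptor only if
#'   nearest / second-nearest distance is strictly below this value.
#' @param mutual also require the match to hold in the reverse direction
#'   (off by default; the standard test is one-directional).
#' @return list of class `match_params`.
#' @export
match_params <- function(dist_ratio = 0.8, mutual = FALSE) {
  stopifnot(dist_ratio > 0, dist_ratio <= 1)
  structure(list(dist_ratio = dist_ratio, mutual = mutual),
            class = "match_params")
}

#' Ratio-test descriptor matching
#'
#' For each row of `a`, finds the nearest and second-nearest rows of `b` in
#' Euclidean distance and emits a pair iff `d1 / d2 < dist_ratio`
#' (one-directional, a -> b). Both sets must hold unit-Euclidean-norm rows
#' (RootSIFT-transformed, or plain SIFT which is unit-normalized by
#' construction); anything else errors. If `b` has fewer than 2 rows there
#' is no second-nearest and no pair is emitted. A second-nearest distance of
#' exactly 0 (duplicate gallery descriptors) yields ratio 1, i.e. rejection.
#' Ties for the second-nearest are broken by the smaller gallery index.
#'
#' @param a,b `descriptor_set`s with unit-norm rows.
#' @param params a [match_params()].
#' @return tibble of class `match_set`: `index_a`, `index_b` (1-based rows
#'   of `a`/`b`), `x_a`, `y_a`, `x_b`, `y_b`, `distance`, `ratio`.
#' @export
match_descriptors <- function(a, b, params = match_params()) {
  stopifnot(inherits(a, "descriptor_set"), inherits(b, "descriptor_set"))
  check_unit_rows(a$vectors)
  check_unit_rows(b$vectors)
  out0 <- tibble(index_a = integer(), index_b = integer(),
                 x_a = double(), y_a = double(),
                 x_b = double(), y_b = double(),
                 distance = double(), ratio = double())
  if (nrow(a$vectors) == 0 || nrow(b$vectors) < 2) return(as_match_set(out0))
  nn <- nearest_two(a$vectors, b$vectors)
  ratio <- ifelse(nn$d2 <= 0, 1, nn$d1 / nn$d2)
  keep <- ratio < params$dist_ratio
  if (params$mutual && any(keep) && nrow(a$vectors) >= 2) {
    rev_nn <- nearest_two(b$vectors, a$vectors)
    rev_ratio <- ifelse(rev_nn$d2 <= 0, 1, rev_nn$d1 / rev_nn$d2)
    keep <- keep & (rev_nn$i1[nn$i1] == seq_len(nrow(a$vectors))) &
      (rev_ratio[nn$i1] < params$dist_ratio)
  }
  idx <- which(keep)
  out <- tibble(
    index_a = idx,
    index_b = nn$i1[idx],
    x_a = a$keypoints$x[idx], y_a = a$keypoints$y[idx],
    x_b = b$keypoints$x[nn$i1[idx]], y_b = b$keypoints$y[nn$i1[idx]],
    distance = nn$d1[idx],
    ratio = ratio[idx]
  )
  as_match_set(out)
}

as_match_set <- function(x) {
  class(x) <- c("match_set", class(x))
  x
}

check_unit_rows <- function(v, tol = 1e-6) {
  if (!nrow(v)) return(invisible(TRUE))
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > tol)) {
    abort("descriptor rows are not unit-norm: apply root_sift() (or use plain unit-normalized SIFT) before matching")
  }
  invisible(TRUE)
}

# nearest and second-nearest neighbours of each row of `a` among rows of `b`,
# squared distances computed via the unit-norm identity d^2 = 2 - 2 a.b
nearest_two <- function(a, b) {
  sim <- tcrossprod(a, b) # cosine similarities
  i1 <- max.col(sim, ties.method = "first")
  s1 <- sim[cbind(seq_len(nrow(sim)), i1)]
  sim[cbind(seq_len(nrow(sim)), i1)] <- -Inf
  i2 <- max.col(sim, ties.method = "first")
  s2 <- sim[cbind(seq_len(nrow(sim)), i2)]
  d <- function(s) sqrt(pmax(2 - 2 * s, 0))
  list(i1 = i1, d1 = d(s1), i2 = i2, d2 = d(s2))
}

#' Serialize descriptor sets and match lists to TSV
#'
#' Descriptor sets use columns `kp_x, kp_y, scale, orientation, d0...d127`;
#' match lists use `index_a, index_b, x_a, y_a, x_b, y_b, distance, ratio`
#' (plus `label` if present).
#'
#' @param x a `descriptor_set` or match tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_descriptors_tsv <- function(x, path) {
  stopifnot(inherits(x, "descriptor_set"))
  v <- x$vectors
  colnames(v) <- paste0("d", seq_len(128) - 1)
  df <- cbind(
    data.frame(kp_x = x$keypoints$x, kp_y = x$keypoints$y,
               scale = x$keypoints$scale, orientation = x$keypoints$orientation),
    as.data.frame(v)
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptors_tsv
#' @export
read_descriptors_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  vec <- as.matrix(df[, paste0("d", 0:127)])
  dimnames(vec) <- NULL
  descriptor_set(
    tibble(x = df$kp_x, y = df$kp_y, scale = df$scale,
           orientation = df$orientation,
           response = rep(NA_real_, nrow(df))),
    vec
  )
}

#' @rdname write_descriptors_tsv
#' @export
write_matches_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
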