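#' Pipeline configuration
#'
#' Bundles every stage's parameters plus protocol options; echoed verbatim
#' into reports so any run can be reproduced exactly.
#'
#' @param preprocess a [preprocess_config()].
#' @param match a [match_params()].
#' @param neighbor a [neighbor_filter_config()].
#' @param lbp an [lbp_filter_config()].
#' @param n_features keypoint budget per image passed to [detect_sift()].
#' @param mask_erosion_px radius (pixels) by which the palm mask is eroded
#'   before keypoint filtering. Enhancement zeroes the background, leaving a
#'   strong artificial rim at the mask boundary; keypoints there describe
#'   the silhouette, not vein texture, so they are excluded from matching.
#'   The full mask still defines centroids and the matching substrate.
#' @param descriptor `"rootsift"` (default) or `"sift"` (plain
#'   unit-normalized descriptors, the comparison baseline).
#' @param mismatch_removal apply the hierarchical filter (disable to score
#'   raw ratio-test matches).
#' @param symmetric score both directions and take the minimum.
#' @param seed master seed echoed into reports.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            match = match_params(),
                            neighbor = neighbor_filter_config(),
                            lbp = lbp_filter_config(),
                            n_features = 400,
                            mask_erosion_px = 8,
                            descriptor = c("rootsift", "sift"),
                            mismatch_removal = TRUE,
                            symmetric = FALSE,
                            seed = 1L) {
  structure(
    list(preprocess = preprocess, match = match, neighbor = neighbor,
         lbp = lbp, n_features = n_features,
         mask_erosion_px = mask_erosion_px,
         descriptor = match.arg(descriptor),
         mismatch_removal = mismatch_removal, symmetric = symmetric,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Extract all per-image features used by matching
#'
#' Runs [preprocess()] and [detect_sift()] once and caches everything pair
#' scoring needs: the enhanced image, mask, descriptor set (both RootSIFT
#' and plain), and the LBP code map. Batch evaluation calls this once per
#' image instead of once per pair.
#'
#' @param img grayscale matrix.
#' @param config a [pipeline_config()].
#' @return list of class `palm_features`, or `NULL` if the image is
#'   unsegmentable (callers treat the score as missing).
#' @export
extract_features <- function(img, config = pipeline_config()) {
  pp <- tryCatch(preprocess(img, config$preprocess), error = function(e) NULL)
  if (is.null(pp)) return(NULL)
  kp_mask <- erode_palm_mask(pp$mask, config$mask_erosion_px)
  raw <- detect_sift(pp$image, kp_mask, n_features = config$n_features)
  structure(
    list(
      image = pp$image, mask = pp$mask,
      raw = raw,
      rootsift = suppressMessages(root_sift(raw)),
      lbp_codes = lbp_code_map(pp$image)
    ),
    class = "palm_features"
  )
}

# match + hierarchical filter between two cached feature objects
score_features <- function(fa, fb, config = pipeline_config()) {
  da <- if (config$descriptor == "rootsift") fa$rootsift else fa$raw
  db <- if (config$descriptor == "rootsift") fb$rootsift else fb$raw
  m <- match_descriptors(da, db, config$match)
  m <- as_filtered_matches(m)
  if (config$mismatch_removal && nrow(m)) {
    m <- hierarchical_filter(m, fa$mask, fb$mask, fa$image, fb$image,
                             neighbor_cfg = config$neighbor,
                             lbp_cfg = config$lbp,
                             codes_a = fa$lbp_codes, codes_b = fb$lbp_codes)
  }
  m
}

#' Match two palm images end-to-end
#'
#' preprocess -> detect -> root transform -> ratio-test match ->
#' hierarchical mismatch removal. The surviving (`kept`) match count is the
#' similarity score.
#'
#' @param img_a,img_b grayscale matrices.
#' @param config a [pipeline_config()].
#' @return list of class `palm_match`: `matches` (a `filtered_matches`
#'   tibble), `score`, `features_a`, `features_b`, `config`.
#' @export
match_palms <- function(img_a, img_b, config = pipeline_config()) {
  fa <- extract_features(img_a, config)
  fb <- extract_features(img_b, config)
  if (is.null(fa) || is.null(fb)) abort("unsegmentable input image")
  m <- score_features(fa, fb, config)
  score <- sum(m$label == "kept")
  if (config$symmetric) {
    m_rev <- score_features(fb, fa, config)
    score <- min(score, sum(m_rev$label == "kept"))
  }
  structure(
    list(matches = m, score = score, features_a = fa, features_b = fb,
         config = config),
    class = "palm_match"
  )
}

#' @export
print.palm_match <- function(x, ...) {
  cat(sprintf("<palm_match> score %d (%d candidate pairs)\n",
              x$score, nrow(x$matches)))
  invisible(x)
}

#' Similarity score of two palm images
#'
#' The number of matches surviving the full pipeline; higher means more
#' similar. Unsegmentable inputs score as `NA` (missing), not 0.
#'
#' @inheritParams match_palms
#' @return nonnegative integer, or `NA` if either image is unsegmentable.
#' @export
similarity_score <- function(img_a, img_b, config = pipeline_config()) {
  res <- tryCatch(match_palms(img_a, img_b, config),
                  error = function(e) NULL)
  if (is.null(res)) return(NA_integer_)
  as.integer(res$score)
}
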