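#' FAR/FRR curves over a set of score records
#'
#' For every integer threshold over the observed score range (plus one step
#' above the maximum): `FAR(t)` = fraction of impostor scores `>= t`,
#' `FRR(t)` = fraction of genuine scores `< t`. FAR is non-increasing and
#' FRR non-decreasing in the threshold.
#'
#' @param records data frame with columns `score` (nonnegative) and
#'   `genuine` (logical); typically from [evaluate_gallery()]. Rows with
#'   `NA` scores are dropped with a warning.
#' @return tibble of class `roc_curve`: `threshold`, `far`, `frr`.
#' @export
far_frr <- function(records) {
  stopifnot(all(c("score", "genuine") %in% names(records)))
  if (anyNA(records$score)) {
    warning("dropping records with missing scores")
    records <- records[!is.na(records$score), , drop = FALSE]
  }
  gen <- records$score[records$genuine]
  imp <- records$score[!records$genuine]
  if (!length(gen) || !length(imp)) {
    abort("need at least one genuine and one impostor record")
  }
  lo <- floor(min(records$score)); hi <- ceiling(max(records$score)) + 1L
  thr <- seq.int(lo, hi)
  curve <- tibble(
    threshold = thr,
    far = vapply(thr, function(t) mean(imp >= t), 0),
    frr = vapply(thr, function(t) mean(gen < t), 0)
  )
  stopifnot(!is.unsorted(-curve$far), !is.unsorted(curve$frr))
  class(curve) <- c("roc_curve", class(curve))
  curve
}

#' Equal error rate of a FAR/FRR curve
#'
#' The operating point where the (piecewise-linearly interpolated) FAR and
#' FRR curves cross. Fully separated score distributions give EER 0;
#' identical distributions give 0.5.
#'
#' @param curve a `roc_curve` from [far_frr()].
#' @return list with `eer` (in `[0, 1]`) and `threshold` (real; the
#'   interpolated crossing point).
#' @export
eer <- function(curve) {
  stopifnot(all(c("threshold", "far", "frr") %in% names(curve)))
  d <- curve$far - curve$frr
  hit <- which(d == 0)
  if (length(hit)) {
    i <- hit[1]
    return(list(eer = curve$far[i], threshold = curve$threshold[i]))
  }
  # FAR starts >= FRR (d >= 0) and ends <= (d <= 0); find the sign change
  i <- which(d[-length(d)] > 0 & d[-1] < 0)[1]
  if (is.na(i)) {
    # degenerate single-point curve
    i <- which.min(abs(d))
    return(list(eer = (curve$far[i] + curve$frr[i]) / 2,
                threshold = curve$threshold[i]))
  }
  s <- d[i] / (d[i] - d[i + 1])
  list(
    eer = curve$far[i] + s * (curve$far[i + 1] - curve$far[i]),
    threshold = curve$threshold[i] + s * (curve$threshold[i + 1] - curve$threshold[i])
  )
}

#' Score a labeled gallery and report FAR/FRR/EER
#'
#' Scores every unordered pair of gallery samples once — all within-identity
#' pairs are genuine, all cross-identity pairs impostor (the all-pairs
#' protocol; set `protocol = "first_enrollment"` to compare every sample
#' only against each identity's first sample). Deterministic given the
#' config and gallery.
#'
#' @param gallery either a directory laid out as
#'   `root/<identity>/<sample>.png`, or a data frame with columns `id`,
#'   `sample`, and `image` (a list-column of grayscale matrices).
#' @param config a [pipeline_config()].
#' @param protocol `"all_pairs"` (default) or `"first_enrollment"`.
#' @param features optional precomputed list of `palm_features` parallel to
#'   the gallery rows (an optimization; computed when missing).
#' @return object of class `palmvein_eval`: list with `records` (tibble
#'   `id_a, sample_a, id_b, sample_b, score, genuine`), `curve`
#'   (a `roc_curve`), `eer`, `eer_threshold`, `n_genuine`, `n_impostor`,
#'   `config`.
#' @export
evaluate_gallery <- function(gallery, config = pipeline_config(),
                             protocol = c("all_pairs", "first_enrollment"),
                             features = NULL) {
  protocol <- match.arg(protocol)
  tab <- load_gallery(gallery)
  if (dplyr::n_distinct(tab$id) < 2 || any(table(tab$id) < 2)) {
    abort("degenerate gallery: need >= 2 identities with >= 2 samples each")
  }
  # order-free protocol: scores do not depend on file order
  tab <- dplyr::arrange(tab, .data$id, .data$sample)
  if (is.null(features)) {
    features <- lapply(tab$image, extract_features, config = config)
  }
  pairs <- utils::combn(nrow(tab), 2)
  if (protocol == "first_enrollment") {
    first <- !duplicated(tab$id)
    keep <- first[pairs[1, ]] | first[pairs[2, ]]
    pairs <- pairs[, keep, drop = FALSE]
  }
  score1 <- function(i, j) {
    if (is.null(features[[i]]) || is.null(features[[j]])) return(NA_integer_)
    m <- score_features(features[[i]], features[[j]], config)
    sum(m$label == "kept")
  }
  records <- tibble(
    id_a = tab$id[pairs[1, ]], sample_a = tab$sample[pairs[1, ]],
    id_b = tab$id[pairs[2, ]], sample_b = tab$sample[pairs[2, ]],
    score = vapply(seq_len(ncol(pairs)),
                   function(k) score1(pairs[1, k], pairs[2, k]), integer(1)),
    genuine = tab$id[pairs[1, ]] == tab$id[pairs[2, ]]
  )
  curve <- far_frr(records)
  e <- eer(curve)
  structure(
    list(records = records, curve = curve, eer = e$eer,
         eer_threshold = e$threshold,
         n_genuine = sum(records$genuine & !is.na(records$score)),
         n_impostor = sum(!records$genuine & !is.na(records$score)),
         config = config),
    class = "palmvein_eval"
  )
}

# accept a gallery directory (root/<id>/<sample>.png) or an in-memory tibble
load_gallery <- function(gallery) {
  if (is.data.frame(gallery)) {
    stopifnot(all(c("id", "sample", "image") %in% names(gallery)))
    return(gallery)
  }
  if (!dir.exists(gallery)) abort(sprintf("gallery directory '%s' not found", gallery))
  ids <- list.dirs(gallery, recursive = FALSE, full.names = FALSE)
  if (!length(ids)) abort("malformed gallery: expected one sub-directory per identity")
  rows <- purrr::map_dfr(ids, function(id) {
    files <- list.files(file.path(gallery, id),
                        pattern = "\\.(png|pgm|jpg|jpeg)$", full.names = TRUE)
    if (!length(files)) abort(sprintf("malformed gallery: identity '%s' has no images", id))
    tibble(id = id,
           sample = tools::file_path_sans_ext(basename(files)),
           path = files)
  })
  rows$image <- lapply(rows$path, read_gray)
  rows
}

#' @export
print.palmvein_eval <- function(x, ...) {
  cat(sprintf(
    "<palmvein_eval> EER %.2f%% at threshold %.2f (%d genuine, %d impostor pairs)\n",
    100 * x$eer, x$eer_threshold, x$n_genuine, x$n_impostor
  ))
  invisible(x)
}

#' Broom-style accessors for evaluation reports
#'
#' `tidy()` returns the ROC curve as a tibble; `glance()` a one-row summary.
#'
#' @param x a `palmvein_eval`.
#' @param ... unused.
#' @export
tidy.palmvein_eval <- function(x, ...) {
  as_tibble(x$curve)
}

#' @rdname tidy.palmvein_eval
#' @export
glance.palmvein_eval <- function(x, ...) {
  tibble(
    eer = x$eer, eer_threshold = x$eer_threshold,
    n_genuine = x$n_genuine, n_impostor = x$n_impostor,
    mean_genuine = mean(x$records$score[x$records$genuine], na.rm = TRUE),
    mean_impostor = mean(x$records$score[!x$records$genuine], na.rm = TRUE)
  )
}

#' Plot a FAR/FRR trade-off curve
#'
#' @param object a `palmvein_eval` or `roc_curve`.
#' @param ... unused.
#' @return a ggplot object: FAR and FRR against the decision threshold with
#'   the EER operating point marked.
#' @export
autoplot.palmvein_eval <- function(object, ...) {
  p <- autoplot.roc_curve(object$curve) +
    ggplot2::geom_point(
      data = data.frame(threshold = object$eer_threshold, rate = object$eer),
      ggplot2::aes(x = .data$threshold, y = .data$rate),
      inherit.aes = FALSE, shape = 4, size = 3
    )
  p + ggplot2::labs(subtitle = sprintf("EER %.2f%%", 100 * object$eer))
}

#' @rdname autoplot.palmvein_eval
#' @export
autoplot.roc_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("far", "frr"),
                              names_to = "rate_type", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$rate,
                                     color = .data$rate_type)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "decision threshold (match count)", y = "error rate",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Write evaluation outputs
#'
#' Scores as TSV, the ROC curve as CSV and the report (EER, thresholds,
#' pair counts, config echo, seed) as JSON.
#'
#' @param x a `palmvein_eval`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(as.data.frame(x$records), file.path(dir, "scores.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(x$curve), file.path(dir, "roc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(eer = x$eer, eer_threshold = x$eer_threshold,
         n_genuine = x$n_genuine, n_impostor = x$n_impostor,
         config = config_to_list(x$config), seed = x$config$seed),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

config_to_list <- function(cfg) {
  rapply(unclass(cfg), function(x) x, how = "list")
}
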