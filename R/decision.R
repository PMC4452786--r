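histogram_matrix <- function(x, k = NULL) {
  X <- if (is.matrix(x)) x
  else if (is.data.frame(x) && "histogram" %in% names(x)) x$histogram
  else if (inherits(x, "bovw_histogram")) matrix(x$counts, 1)
  else if (is.numeric(x) && is.null(dim(x))) matrix(x, 1)
  else stop_invalid("expected histograms (matrix, tibble or bovw_histogram)")
  if (!is.null(k) && ncol(X) != k) {
    stop_invalid(sprintf("histogram dimension %d does not match model k = %d",
                         ncol(X), k))
  }
  X
}

#' Train a per-lesion binary decision model
#'
#' Fits a regularized maximum-margin linear scorer (linear-kernel SVM, no
#' feature rescaling) on BoVW histograms: positives are images carrying the
#' lesion family, negatives are normal images. The score of an image is its
#' signed distance direction to the separating boundary (`w . h + b`),
#' oriented so higher means more lesion-like; the default operating
#' threshold is 0. The median training-normal score is stored so the two
#' detectors' scores can be standardized before fusion.
#'
#' @param histograms Histogram tibble (or n x k matrix).
#' @param labels Logical vector: `TRUE` where the lesion is present.
#' @param lesion `"bright"` or `"red"`.
#' @param cost Soft-margin regularization parameter C.
#' @param threshold Operating threshold on the score.
#' @return A `bovw_detector`: list with `lesion`, `w`, `b`, `threshold`,
#'   `normal_median`, `codebook_ref`, `training_meta`.
#' @export
train_detector <- function(histograms, labels, lesion = c("bright", "red"),
                           cost = 1, threshold = 0) {
  lesion <- match.arg(lesion)
  X <- histogram_matrix(histograms)
  y <- as.logical(labels)
  if (length(y) != nrow(X)) stop_invalid("one label per histogram row required")
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop_invalid("need at least 2 examples of each class", "bovw_data_error")
  }
  fit <- e1071::svm(x = X, y = factor(y, levels = c("FALSE", "TRUE")),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  s <- as.numeric(X %*% w) + b
  if (mean(s[y]) < mean(s[!y])) { w <- -w; b <- -b; s <- -s }
  structure(list(lesion = lesion, w = w, b = b, threshold = threshold,
                 normal_median = stats::median(s[!y]),
                 codebook_ref = attr(histograms, "codebook_ref") %||% NA_character_,
                 training_meta = sprintf("n=%d pos=%d cost=%g",
                                         length(y), sum(y), cost)),
            class = "bovw_detector")
}

#' @export
print.bovw_detector <- function(x, ...) {
  cat(sprintf("<bovw_detector> lesion=%s k=%d threshold=%g (%s)\n",
              x$lesion, length(x$w), x$threshold, x$training_meta))
  invisible(x)
}

#' Score histograms with a trained detector
#'
#' Deterministic linear score `w . h + b`; higher = more lesion-like. A
#' zero (empty-image) histogram scores as the bias term alone.
#'
#' @param model A `bovw_detector`.
#' @param histograms Histogram tibble, matrix, vector or `bovw_histogram`.
#' @param standardize Subtract the model's median training-normal score
#'   (used before multi-lesion fusion).
#' @return Numeric score vector.
#' @export
score_detector <- function(model, histograms, standardize = FALSE) {
  X <- histogram_matrix(histograms, k = length(model$w))
  s <- as.numeric(X %*% model$w) + model$b
  if (standardize) s <- s - model$normal_median
  s
}

#' Multi-lesion fusion rule
#'
#' An image is referable when either single-lesion detector flags it; it is
#' called normal only when both detectors agree it is normal (the rule that
#' minimises false negatives in screening).
#'
#' @param flag_bright,flag_red Logical flags from the two detectors.
#' @return Logical: referable.
#' @export
fuse <- function(flag_bright, flag_red) {
  as.logical(flag_bright) | as.logical(flag_red)
}

#' Continuous multi-lesion score
#'
#' The maximum of the two standardized per-detector scores. Thresholding
#' this at `t` is exactly the OR of the per-detector flags at `t`
#' (`max(a, b) > t` iff `a > t | b > t`), so the fused ROC sweeps the same
#' operating points as the fusion rule.
#'
#' @param score_bright,score_red Standardized per-detector scores (zero
#'   median on training normals; see [score_detector()]).
#' @return Numeric fused score.
#' @export
fuse_score <- function(score_bright, score_red) {
  pmax(score_bright, score_red)
}

#' Screen a set of images with both detectors
#'
#' @param hists_bright,hists_red Histogram tibbles encoded with each
#'   detector's codebook (same images, same order).
#' @param model_bright,model_red Trained `bovw_detector`s. Histogram/model
#'   codebook identifiers must match.
#' @return A tibble `id, score_bright, score_red, flag_bright, flag_red,
#'   referable, fused_score` (scores raw; `fused_score` from standardized
#'   scores).
#' @export
screen_images <- function(hists_bright, hists_red, model_bright, model_red) {
  if (!identical(hists_bright$image_id, hists_red$image_id)) {
    stop_invalid("bright and red histograms must cover the same images in order")
  }
  for (pair in list(list(h = hists_bright, m = model_bright),
                    list(h = hists_red, m = model_red))) {
    href <- attr(pair$h, "codebook_ref"); mref <- pair$m$codebook_ref
    if (!is.null(href) && !is.na(mref) && href != mref) {
      stop_invalid(sprintf("codebook mismatch: histograms %s vs model %s",
                           href, mref), "bovw_consistency_error")
    }
  }
  sb <- score_detector(model_bright, hists_bright)
  sr <- score_detector(model_red, hists_red)
  fb <- sb > model_bright$threshold
  fr <- sr > model_red$threshold
  tibble::tibble(id = hists_bright$image_id,
                 score_bright = sb, score_red = sr,
                 flag_bright = fb, flag_red = fr,
                 referable = fuse(fb, fr),
                 fused_score = fuse_score(sb - model_bright$normal_median,
                                          sr - model_red$normal_median))
}

#' Save / load a trained detector
#'
#' Plain-text container: header
#' `bovw_detector <lesion> <k> <b> <threshold> <normal_median> <codebook_ref>`,
#' a `meta` line, then the weight vector (one `%.17g` value per line);
#' round-trips bit-exact.
#'
#' @param model A `bovw_detector`.
#' @param path File path.
#' @return `path` (save) or the reloaded `bovw_detector` (load).
#' @export
save_detector <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("bovw_detector\t%s\t%d\t%.17g\t%.17g\t%.17g\t%s",
                     model$lesion, length(model$w), model$b, model$threshold,
                     model$normal_median, model$codebook_ref), con)
  writeLines(paste0("meta\t", model$training_meta), con)
  writeLines(sprintf("%.17g", model$w), con)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "bovw_detector")) {
    stop_invalid(sprintf("'%s' is not a detector file", path), "bovw_format_error")
  }
  hdr <- strsplit(lines[1], "\t")[[1]]
  if (length(hdr) != 7) stop_invalid("malformed detector header", "bovw_format_error")
  k <- as.integer(hdr[3])
  w <- as.numeric(lines[-(1:2)])
  if (length(w) != k || anyNA(w)) {
    stop_invalid("detector file truncated or malformed weights", "bovw_format_error")
  }
  structure(list(lesion = hdr[2], w = w, b = as.numeric(hdr[4]),
                 threshold = as.numeric(hdr[5]),
                 normal_median = as.numeric(hdr[6]), codebook_ref = hdr[7],
                 training_meta = sub("^meta\t?", "", lines[2])),
            class = "bovw_detector")
}
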