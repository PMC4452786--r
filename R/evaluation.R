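#' ROC curve by threshold sweep
#'
#' Sweeps the cut-off over the distinct score values (for curve thresholds
#' an image counts positive when its score is `>=` the threshold), grouping
#' tied scores into single steps, with `+Inf`/`-Inf` endpoints so the curve
#' runs from (0, 0) to (1, 1). The AUC is the trapezoidal area, which under this
#' tie-grouping equals the Mann-Whitney pair-counting statistic with ties
#' scored 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) true labels; both classes must occur.
#' @return A `roc_curve`: list with `points` (tibble `fpr, tpr, threshold`,
#'   threshold descending), `auc`, `n_pos`, `n_neg`.
#' @export
compute_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop_invalid("`scores` and `labels` must be equal-length and complete")
  }
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) {
    stop_invalid("ROC undefined: need at least one positive and one negative",
                 "bovw_roc_error")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)     # last row of each tied block
  points <- tibble::tibble(
    fpr = c(0, fp[last] / N),
    tpr = c(0, tp[last] / P),
    threshold = c(Inf, s[last])
  )
  # terminal point: everything positive
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1) {
    points <- dplyr::bind_rows(points, tibble::tibble(fpr = 1, tpr = 1,
                                                      threshold = -Inf))
  } else {
    points$threshold[nrow(points)] <- -Inf
  }
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = P, n_neg = N),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d pos / %d neg, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_abline labs
#'   coord_equal theme_minimal geom_line facet_wrap
#' @export
ggplot2::autoplot

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_path(colour = "#00548f") +
    coord_equal() +
    labs(x = "False-positive rate (1 - specificity)",
         y = "True-positive rate (sensitivity)",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Best operating point at a specificity floor
#'
#' Among thresholds whose specificity (`1 - fpr`) is at least the target,
#' returns the one maximizing sensitivity; ties resolve to the higher
#' specificity. Always feasible because the curve contains the
#' call-nothing-positive endpoint.
#'
#' @param roc A `roc_curve`.
#' @param target_specificity Specificity floor in `[0, 1]`.
#' @return One-row tibble `threshold, sensitivity, specificity`.
#' @export
operating_point <- function(roc, target_specificity) {
  pts <- roc$points
  feas <- pts[1 - pts$fpr >= target_specificity - 1e-12, ]
  best <- feas[order(-feas$tpr, feas$fpr), ][1, ]
  tibble::tibble(threshold = best$threshold, sensitivity = best$tpr,
                 specificity = 1 - best$fpr)
}

#' Confusion-matrix screening metrics
#'
#' Sensitivity is the true-positive rate over lesion-positive images,
#' specificity the true-negative rate over normals. A zero denominator
#' yields `NA` (undefined), never 0.
#'
#' @param flags Logical predicted flags.
#' @param labels Logical true labels.
#' @return One-row tibble `tp, fp, tn, fn, sensitivity, specificity, accuracy`.
#' @export
confusion_metrics <- function(flags, labels) {
  flags <- as.logical(flags); labels <- as.logical(labels)
  if (length(flags) != length(labels)) {
    stop_invalid("`flags` and `labels` must have equal length")
  }
  tp <- sum(flags & labels); fp <- sum(flags & !labels)
  tn <- sum(!flags & !labels); fn <- sum(!flags & labels)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = safe_div(tp, tp + fn),
                 specificity = safe_div(tn, tn + fp),
                 accuracy = safe_div(tp + tn, tp + tn + fp + fn))
}
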