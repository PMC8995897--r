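#' Threshold classification metrics from a confusion table
#'
#' Accuracy, precision, recall and F1 for binary labels/predictions coded
#' 0/1. Degenerate denominators (no predicted positives, no true
#' positives, or an undefined F1) yield 0 with a warning rather than NaN.
#'
#' @param labels Integer vector of true labels (0/1).
#' @param predicted Integer vector of predicted labels (0/1), same length.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `n_pos`,
#'   `n_neg`.
#' @export
confusion_metrics <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predicted have different lengths")
  }
  if (length(labels) == 0L) stop("Empty input")
  stopifnot(all(labels %in% c(0L, 1L)), all(predicted %in% c(0L, 1L)))
  tp <- sum(labels == 1L & predicted == 1L)
  fp <- sum(labels == 0L & predicted == 1L)
  fn <- sum(labels == 1L & predicted == 0L)
  tn <- sum(labels == 0L & predicted == 0L)
  guarded <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0")
      0
    } else num / den
  }
  precision <- guarded(tp, tp + fp, "precision")
  recall <- guarded(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (precision + recall = 0); returning 0")
    0
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1,
       n_pos = sum(labels == 1L), n_neg = sum(labels == 0L))
}

#' ROC curve and area
#'
#' Thresholds sweep the distinct scores in descending order; tied scores
#' collapse into a single step. The area is the trapezoidal integral,
#' which equals the Mann-Whitney probability that a random positive
#' outscores a random negative (ties counted half).
#'
#' @param labels True labels (0/1), both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return List with `points` (data.frame `fpr`, `tpr`, starting at (0,0))
#'   and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  check_scores(labels, scores)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("ROC needs both classes present")
  }
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  # indices closing each tie group
  grp_end <- which(!duplicated(sc, fromLast = TRUE))
  ctp <- cumsum(lab == 1L)[grp_end]
  cfp <- cumsum(lab == 0L)[grp_end]
  tpr <- c(0, ctp / sum(labels == 1L))
  fpr <- c(0, cfp / sum(labels == 0L))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and area
#'
#' Same descending threshold sweep as [roc_curve()]. The area uses
#' step-wise (achievable-precision) integration over recall increments —
#' the average-precision convention — not trapezoids, because linear
#' interpolation between PR points overstates attainable precision.
#'
#' @inheritParams roc_curve
#' @return List with `points` (data.frame `recall`, `precision`) and
#'   `auc`.
#' @export
pr_curve <- function(labels, scores) {
  check_scores(labels, scores)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("PR curve needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  grp_end <- which(!duplicated(sc, fromLast = TRUE))
  ctp <- cumsum(lab == 1L)[grp_end]
  npred <- grp_end
  recall <- ctp / n_pos
  precision <- ctp / npred
  auc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision), auc = auc)
}

check_scores <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores have different lengths")
  }
  if (length(labels) == 0L) stop("Empty input")
  stopifnot(all(labels %in% c(0L, 1L)), is.numeric(scores), !anyNA(scores))
}

#' Full evaluation report for scored pairs
#'
#' Combines the threshold metrics (at the given decision threshold) with
#' the threshold-free AUC_ROC and AUC_PR.
#'
#' @param labels True labels (0/1).
#' @param scores Numeric scores in arbitrary units.
#' @param threshold Decision threshold: predicted positive iff
#'   `score > threshold`. For probability scores use 0.5; for similarity
#'   scores pick with [best_threshold()] on training data.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc_roc`,
#'   `auc_pr`, `n_pos`, `n_neg`, `threshold`.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  cm <- confusion_metrics(labels, as.integer(scores > threshold))
  roc <- roc_curve(labels, scores)
  pr <- pr_curve(labels, scores)
  c(cm[c("accuracy", "precision", "recall", "f1")],
    list(auc_roc = roc$auc, auc_pr = pr$auc,
         n_pos = cm$n_pos, n_neg = cm$n_neg, threshold = threshold))
}

#' Accuracy-maximizing decision threshold
#'
#' Scans midpoints between consecutive distinct scores (plus sentinels
#' below/above the score range) and returns the threshold with the highest
#' accuracy on the given data. Select the threshold on training scores,
#' then evaluate held-out pairs at that fixed threshold.
#'
#' @inheritParams roc_curve
#' @return A single numeric threshold.
#' @export
best_threshold <- function(labels, scores) {
  check_scores(labels, scores)
  s <- sort(unique(scores))
  cand <- c(s[[1]] - 1, if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2,
            s[[length(s)]] + 1)
  acc <- vapply(cand, function(th) mean((scores > th) == (labels == 1L)), numeric(1))
  cand[[which.max(acc)]]
}
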