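#' Confusion counts at a decision threshold
#'
#' Predicts class 1 (good) when `score >= threshold` and tallies true/false
#' positives/negatives with class 1 as the positive class.
#'
#' @param y_true Binary vector of true labels (0/1).
#' @param scores Vector of predicted scores or probabilities.
#' @param threshold Decision cutoff (default 0.5).
#' @return An object of class `ppgq_confusion`: list with `TP`, `TN`, `FP`,
#'   `FN`. The four counts always sum to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, scores, threshold = 0.5) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(scores)) {
    stop("'y_true' and 'scores' must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) stop("'y_true' must be binary",
                                      call. = FALSE)
  pred <- as.integer(scores >= threshold)
  structure(
    list(TP = sum(pred == 1L & y_true == 1),
         TN = sum(pred == 0L & y_true == 0),
         FP = sum(pred == 1L & y_true == 0),
         FN = sum(pred == 0L & y_true == 1)),
    class = "ppgq_confusion"
  )
}

#' @export
print.ppgq_confusion <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d TN=%d FP=%d FN=%d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Threshold classification metrics from confusion counts
#'
#' Evaluates accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)` and the F1 score (harmonic mean of precision and
#' recall). A ratio with zero denominator is returned as 0 with a warning.
#'
#' @param counts A [confusion_counts()] object.
#' @return Named list with `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' compute_metrics(structure(list(TP = 3, TN = 4, FP = 1, FN = 2),
#'                           class = "ppgq_confusion"))
#' @export
compute_metrics <- function(counts) {
  if (!inherits(counts, "ppgq_confusion")) {
    stop("'counts' must come from confusion_counts()", call. = FALSE)
  }
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("no evaluated samples", call. = FALSE)
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what))
      0
    } else num / den
  }
  precision <- safe_ratio(counts$TP, counts$TP + counts$FP, "precision")
  recall <- safe_ratio(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 undefined (zero precision and recall); returning 0")
    0
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = (counts$TP + counts$TN) / total,
       precision = precision, recall = recall, f1 = f1)
}

#' Empirical ROC curve
#'
#' One `(FPR, TPR)` point per distinct score threshold, from `(0, 0)` to
#' `(1, 1)`; tied scores are grouped so ties contribute diagonal segments.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `fpr` and `tpr`, both monotone
#'   non-decreasing.
#' @export
roc_points <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("'y_true' and 'scores' must have equal length", call. = FALSE)
  }
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  if (np == 0L || nn == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  ys <- y_true[o]
  ss <- scores[o]
  keep <- c(diff(ss) != 0, TRUE)  # last index of each tied score group
  tp <- cumsum(ys)[keep]
  fp <- cumsum(1 - ys)[keep]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the empirical ROC over all distinct score
#' thresholds. Equals the probability that a random positive outscores a
#' random negative, with ties counted half.
#'
#' @param y_true Binary vector (both classes must be present).
#' @param scores Predicted scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  pts <- roc_points(y_true, scores)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Full evaluation of a classifier on labelled data
#'
#' @param net A `ppgq_net`.
#' @param X Input matrix (one preprocessed segment per row) or a
#'   `ppg_dataset`.
#' @param y Binary labels (ignored when `X` is a dataset).
#' @param threshold Decision threshold for the thresholded metrics.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `roc_points` and the underlying `counts`.
#' @export
evaluate_model <- function(net, X, y = NULL, threshold = 0.5) {
  if (inherits(X, "ppg_dataset")) {
    m <- dataset_matrix(X)
    X <- m$x; y <- m$y
  }
  p <- net_forward(net, X)$prob
  counts <- confusion_counts(y, p, threshold)
  out <- compute_metrics(counts)
  out$auc <- roc_auc(y, p)
  out$roc_points <- roc_points(y, p)
  out$counts <- counts
  out
}
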