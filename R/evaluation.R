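#' Evaluate binary neutral/active predictions
#'
#' Builds the 2x2 confusion matrix (rows = true class, columns = predicted),
#' accuracy, and precision/recall with the active state (label 1) as the
#' positive class.  When class-1 scores are supplied, the precision-recall
#' curve is traced by sweeping every unique score as a threshold, counting
#' `score >= threshold` as a positive prediction; a final threshold below
#' the minimum score is included, at which recall is 1 and precision equals
#' the prevalence of the active class.
#'
#' @param true_labels Integer 0/1 vector of ground-truth labels.
#' @param predicted_labels Integer 0/1 vector of predictions.
#' @param scores Optional numeric vector of class-1 probabilities used for
#'   the precision-recall curve.
#' @return An object of class `eda_eval`: a list with `confusion_matrix`,
#'   `accuracy`, `precision`, `recall`, `pr_curve` (data frame with columns
#'   `threshold`, `recall`, `precision`, or `NULL`), `n` and `undefined`
#'   (names of metrics that are undefined -- e.g. precision when nothing is
#'   predicted positive -- and therefore reported as `NaN`).
#' @examples
#' evaluate_classifier(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
evaluate_classifier <- function(true_labels, predicted_labels,
                                scores = NULL) {
  truth <- as.integer(true_labels)
  pred <- as.integer(predicted_labels)
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(pred)) {
    stop("true and predicted labels must have equal length")
  }
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  if (!is.null(scores) && length(scores) != length(truth)) {
    stop("scores must match the label length")
  }
  cm <- matrix(0L, 2L, 2L,
               dimnames = list(true = c("neutral", "active"),
                               predicted = c("neutral", "active")))
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  n <- length(truth)
  tp <- cm[2L, 2L]
  undefined <- character(0)
  precision <- if (sum(cm[, 2L]) == 0L) {
    undefined <- c(undefined, "precision")
    NaN
  } else {
    tp / sum(cm[, 2L])
  }
  recall <- if (sum(cm[2L, ]) == 0L) {
    undefined <- c(undefined, "recall")
    NaN
  } else {
    tp / sum(cm[2L, ])
  }
  pr <- if (is.null(scores)) NULL else pr_curve(truth, as.numeric(scores))
  structure(list(
    confusion_matrix = cm,
    accuracy = sum(diag(cm)) / n,
    precision = precision,
    recall = recall,
    pr_curve = pr,
    n = n,
    undefined = undefined
  ), class = "eda_eval")
}

# Precision-recall pairs over descending unique thresholds (>= rule), with a
# final all-positive point.
pr_curve <- function(truth, scores) {
  thresholds <- c(sort(unique(scores), decreasing = TRUE),
                  min(scores) - 1)
  n_pos <- sum(truth == 1L)
  out <- data.frame(threshold = thresholds, recall = NA_real_,
                    precision = NA_real_)
  for (i in seq_along(thresholds)) {
    pred_pos <- scores >= thresholds[i]
    tp <- sum(pred_pos & truth == 1L)
    out$recall[i] <- if (n_pos == 0L) NaN else tp / n_pos
    out$precision[i] <- if (sum(pred_pos) == 0L) NaN else tp / sum(pred_pos)
  }
  out
}

#' @export
print.eda_eval <- function(x, digits = 4, ...) {
  cat(sprintf("Binary EDA evaluation on %d sequences\n", x$n))
  print(x$confusion_matrix)
  cat(sprintf("accuracy  %.*f\n", digits, x$accuracy))
  cat(sprintf("precision %.*f (positive = active)\n", digits, x$precision))
  cat(sprintf("recall    %.*f\n", digits, x$recall))
  if (length(x$undefined) > 0L) {
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot the precision-recall curve
#'
#' @param x An `eda_eval` containing a PR curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eda_eval <- function(x, ...) {
  if (is.null(x$pr_curve)) stop("no scores were supplied; no PR curve")
  ok <- is.finite(x$pr_curve$recall) & is.finite(x$pr_curve$precision)
  graphics::plot(x$pr_curve$recall[ok], x$pr_curve$precision[ok],
                 type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "recall", ylab = "precision", ...)
  invisible(x)
}
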