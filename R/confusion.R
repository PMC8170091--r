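# Confusion-matrix utilities and the packaged hardware reference matrix.

#' Build a confusion matrix
#'
#' Rows are the true classes, columns the predicted classes. Predictions of
#' `NA` (no-decision in the ISI readout) are collected in an extra
#' `no_decision` column when present.
#'
#' @param truth 0-based true class indices.
#' @param predicted 0-based predicted class indices (`NA` allowed).
#' @param classes class labels, in index order.
#' @return Integer matrix with dimnames; rows sum to the per-class sample
#'   counts.
#' @export
confusion_matrix <- function(truth, predicted,
                             classes = as.character(seq_len(max(truth) + 1) - 1)) {
  n <- length(classes)
  stopifnot(length(truth) == length(predicted))
  has_nd <- anyNA(predicted)
  cm <- matrix(0L, n, n + has_nd,
               dimnames = list(truth = classes,
                               predicted = c(classes,
                                             if (has_nd) "no_decision")))
  for (i in seq_along(truth)) {
    col <- if (is.na(predicted[i])) n + 1L else predicted[i] + 1L
    cm[truth[i] + 1L, col] <- cm[truth[i] + 1L, col] + 1L
  }
  cm
}

#' Accuracy of a confusion matrix, in percent
#'
#' `100 * trace / total`; any extra columns (e.g. `no_decision`) count
#' toward the total but never the trace.
#'
#' @param cm confusion matrix (rows = truth).
#' @return accuracy in percent.
#' @export
confusion_accuracy <- function(cm) {
  n <- nrow(cm)
  100 * sum(diag(cm[, seq_len(n), drop = FALSE])) / sum(cm)
}

#' Packaged reference confusion matrix for the 4-gesture task
#'
#' The test-set confusion matrix reported for the on-chip classification of
#' the 4-class radar gesture dataset (hello / toward / horizontal /
#' background), shipped as a plain-text fixture.
#'
#' @return 4x4 integer matrix, rows = truth.
#' @examples
#' confusion_accuracy(gesture_reference_confusion())
#' @export
gesture_reference_confusion <- function() {
  path <- system.file("extdata", "gesture_confusion_reference.csv",
                      package = "eventsnn", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1)
  as.matrix(df)
}
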