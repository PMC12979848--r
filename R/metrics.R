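# Internal ROC / threshold metrics: correctness-critical numbers are
# computed here without any external ML dependency.

#' ROC area under the curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random positive outscores a random negative, counting ties as
#' one-half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) ground-truth labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' One row per distinct score threshold (descending), plus the (0,0) anchor.
#'
#' @inheritParams roc_auc
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n_pos <- sum(l == 1)
  n_neg <- sum(l == 0)
  keep <- c(which(diff(s) != 0), length(s))
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, cumsum(l == 0)[keep] / n_neg),
    tpr = c(0, cumsum(l == 1)[keep] / n_pos)
  )
}

#' Threshold classification metrics
#'
#' @inheritParams roc_auc
#' @param threshold scores `>=` threshold are called positive.
#' @return Tibble with one row: `threshold`, `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`, `n`. Precision is `NA` when nothing is called
#'   positive.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  called <- as.integer(scores >= threshold)
  tp <- sum(called == 1 & labels == 1)
  fp <- sum(called == 1 & labels == 0)
  fn <- sum(called == 0 & labels == 1)
  tn <- sum(called == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(
    threshold = threshold,
    accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall, f1 = f1,
    auc = roc_auc(scores, labels), n = length(labels)
  )
}
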