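# Evaluation metrics: ACC, AUC (mid-rank Mann-Whitney), precision, recall.

#' Classification metrics for one evaluation
#'
#' AUC is the Mann-Whitney rank statistic with mid-rank tie handling (the
#' probability that a random positive outscores a random negative, ties
#' counted half), which makes it invariant to monotone score transforms.
#' ACC, precision and recall are computed at `threshold` (score >=
#' threshold predicts the positive class).  Precision is reported as 0 with
#' `precision_defined = FALSE` when there are no positive predictions.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Real score vector of the same length.
#' @param threshold Decision threshold.
#' @return One-row tibble: `acc`, `auc`, `precision`, `recall`, `n_pos`,
#'   `n_neg`, `threshold`, `precision_defined`.
#' @export
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("Labels must be 0/1.")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    warn("AUC undefined: only one class present; reporting NA.")
    auc <- NA_real_
  } else {
    r <- rank(scores)  # mid-ranks for ties
    auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision_defined <- (tp + fp) > 0L
  tibble(
    acc = mean(pred == labels),
    auc = auc,
    precision = if (precision_defined) tp / (tp + fp) else 0,
    recall = if (n_pos > 0L) tp / (tp + fn) else 0,
    n_pos = n_pos, n_neg = n_neg,
    threshold = threshold,
    precision_defined = precision_defined
  )
}
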