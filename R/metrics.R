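#' Rank-statistic area under the ROC curve
#'
#' Mann-Whitney form with ties counted one half: the returned value equals
#' the probability that a uniformly chosen case outscores a uniformly
#' chosen control, with ties contributing 1/2.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Interpolation-free sum over score thresholds:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` where `P_k`, `R_k` are precision and
#' recall after admitting all samples scoring at or above the k-th distinct
#' score (descending).
#'
#' @inheritParams compute_auc
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0 || n_pos == length(labels)) {
    stop("average precision undefined: both classes must be present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_group]; fp <- fp[last_of_group]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Full metric panel at a fixed decision threshold
#'
#' AUC and average precision from the continuous scores, plus sensitivity,
#' specificity, accuracy and F1 from the confusion matrix obtained by
#' calling `score >= threshold` a case.
#'
#' @inheritParams compute_auc
#' @param threshold Decision threshold on the score (default 0.5,
#'   appropriate for calibrated probabilities).
#' @return Named numeric vector: `auc`, `sensitivity`, `specificity`,
#'   `accuracy`, `f1`, `average_precision`.
#' @export
metric_panel <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  c(auc = compute_auc(scores, labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
    average_precision = average_precision(scores, labels))
}

# stratified fold assignment: within each class, fold labels 1..k are
# recycled over a random permutation, so fold class counts differ by at
# most one
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop("cv configuration error: class ", cls, " has fewer samples (",
           length(idx), ") than folds (", k, ")")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
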