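# Ranking and hard-call classification metrics.

#' Area under the ROC curve by pair counting
#'
#' Computes AUC as the probability that a randomly chosen case outscores a
#' randomly chosen control, with ties counting one half:
#' `P(s_case > s_control) + 0.5 P(s_case = s_control)`. Implemented through
#' midranks, which is algebraically identical to exhaustive pair counting.
#'
#' @param scores Numeric case-scores (higher = more case-like).
#' @param labels 0/1 labels aligned with `scores` (1 = case).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_input("scores/labels length mismatch.")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_input("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision over the ranking of scores: precision is evaluated at
#' each distinct score threshold and weighted by the recall gained there.
#' Tied scores are treated as a single threshold.
#'
#' @inheritParams compute_auc
#' @return AUPRC in \[0, 1\].
#' @export
compute_auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L || sum(labels == 0L) == 0L) stop_input("Both classes must be present.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_g)
  npred <- cumsum(n_g)
  prec <- tp / npred
  rec_gain <- tp_g / n1
  sum(prec * rec_gain)
}

# Precision / recall / F1 from hard calls (positive class = case). When no
# sample is called positive, precision and F1 are reported as 0.
hard_call_metrics <- function(calls, labels) {
  labels <- as.integer(labels)
  tp <- sum(calls == 1L & labels == 1L)
  fp <- sum(calls == 1L & labels == 0L)
  fn <- sum(calls == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

# All five evaluation metrics from continuous scores plus hard calls.
score_metrics <- function(scores, calls, labels) {
  c(
    auc = compute_auc(scores, labels),
    auprc = compute_auprc(scores, labels),
    hard_call_metrics(calls, labels)
  )
}
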