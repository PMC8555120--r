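# Score-based binary-classification evaluation for virtual screening:
# confusion counts, TPR/FPR, ROC curve, AUROC (exact tie handling via the
# Mann-Whitney correspondence), precision/recall/F1.

.check_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  if (length(scores) < 1L) stop("empty score vector")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  invisible(TRUE)
}

#' Confusion counts at a score threshold
#'
#' A pair is predicted positive iff its score is at or above the threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 true labels, same length.
#' @param threshold decision threshold (default 0.5, the natural softmax
#'   boundary).
#' @return object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN` (their sum equals the number of pairs).
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  .check_scores(scores, labels)
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0),
                 FN = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN,
              x$FN))
  invisible(x)
}

#' True positive rate
#'
#' `TPR = TP / (TP + FN)`: the proportion of positives correctly identified
#' as positive. Undefined (NA, with a warning) when there are no positives.
#'
#' @param counts a [confusion_at_threshold()] result.
#' @return numeric in `[0, 1]`, or `NA`.
#' @export
tpr <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) {
    warning("TPR undefined: no positive examples")
    return(NA_real_)
  }
  counts$TP / den
}

#' False positive rate
#'
#' `FPR = FP / (FP + TN)`: the proportion of negatives incorrectly
#' identified as positive. Undefined (NA, with a warning) when there are no
#' negatives.
#'
#' @inheritParams tpr
#' @return numeric in `[0, 1]`, or `NA`.
#' @export
fpr <- function(counts) {
  den <- counts$FP + counts$TN
  if (den == 0) {
    warning("FPR undefined: no negative examples")
    return(NA_real_)
  }
  counts$FP / den
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct score values from high
#' to low (tied scores grouped, so ties appear as diagonal segments) and
#' returns the (FPR, TPR) path from (0, 0) to (1, 1).
#'
#' @inheritParams confusion_at_threshold
#' @return data frame with non-decreasing columns `fpr` and `tpr`.
#' @export
roc_points <- function(scores, labels) {
  .check_scores(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_classed("pocketgnn_auroc_undefined",
                 "ROC requires both classes present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the tie-grouped ROC path; with that grouping
#' the result equals the normalized Mann-Whitney statistic, i.e. the
#' probability that a random positive outranks a random negative, counting
#' ties as 1/2.
#'
#' @inheritParams confusion_at_threshold
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1L) + tail(pts$tpr, -1L)) / 2)
}

#' Precision, recall and F1 at a threshold
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. When `TP = 0` the
#' F1 (and any 0/0 component) is defined as 0, the standard convention that
#' keeps per-target tables total.
#'
#' @inheritParams confusion_at_threshold
#' @return list with `precision`, `recall`, `f1`.
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_at_threshold(scores, labels, threshold)
  precision <- if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP)
  recall <- if (cc$TP + cc$FN == 0) 0 else cc$TP / (cc$TP + cc$FN)
  f1 <- if (cc$TP == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Full evaluation report for a scored pair list
#'
#' @inheritParams confusion_at_threshold
#' @return object of class `eval_report`: `auroc`, `precision`, `recall`,
#'   `f1`, `confusion` (at `threshold`) and `roc` (the ROC points).
#' @export
eval_report <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_at_threshold(scores, labels, threshold)
  f <- f1_score(scores, labels, threshold)
  structure(list(auroc = auroc(scores, labels), precision = f$precision,
                 recall = f$recall, f1 = f$f1, confusion = cc,
                 roc = roc_points(scores, labels), threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUROC %.4f | F1 %.4f (precision %.4f, recall %.4f) @ threshold %g\n",
              x$auroc, x$f1, x$precision, x$recall, x$threshold))
  print(x$confusion)
  invisible(x)
}

#' Per-target evaluation table
#'
#' Evaluates each target's scores separately and appends an `Average` row,
#' mirroring the usual per-target virtual-screening report layout.
#'
#' @param df data frame with columns `target_id`, `score`, `label`.
#' @param threshold decision threshold for F1.
#' @return data frame with columns `target_id`, `auroc`, `f1`.
#' @export
evaluate_targets <- function(df, threshold = 0.5) {
  stopifnot(all(c("target_id", "score", "label") %in% names(df)))
  ids <- unique(df$target_id)
  rows <- lapply(ids, function(id) {
    sub <- df[df$target_id == id, ]
    data.frame(target_id = id, auroc = auroc(sub$score, sub$label),
               f1 = f1_score(sub$score, sub$label, threshold)$f1)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(target_id = "Average", auroc = mean(out$auroc),
                        f1 = mean(out$f1)))
}
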