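# Detection scoring: confusion counts against ground truth, the standard
# precision/recall/F1/FPR metrics, and PR/ROC curves with AUC.

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in detection order: a detection is a true
#' positive iff its centroid lies within `truth radius + slack` voxels of
#' the center of a still-unmatched truth record (the nearest such truth is
#' taken). Unmatched detections are false positives; unmatched truths are
#' false negatives. True negatives are not defined by matching alone
#' (`TN = NA`); for the iterative detector the convention is to count
#' correctly rejected candidate targets, see [run_benchmark()].
#'
#' @param detections list of detections (each with `$centroid`) or a
#'   matrix/data.frame of centroids with columns (z, y, x).
#' @param truth list of truth records (each with `$center`, `$radius`).
#' @param slack matching slack in voxels.
#' @return List of class `aneuscan_confusion`: `TP`, `FP`, `FN`,
#'   `TN = NA`, and `matched` (per-detection truth index or NA).
#' @export
match_detections <- function(detections, truth, slack = 1.0) {
  cents <- if (is.matrix(detections) || is.data.frame(detections)) {
    as.matrix(detections)
  } else {
    if (length(detections) == 0) matrix(numeric(), ncol = 3)
    else do.call(rbind, lapply(detections, function(d) d$centroid))
  }
  nd <- nrow(cents); nt <- length(truth)
  used <- rep(FALSE, nt)
  matched <- rep(NA_integer_, nd)
  for (i in seq_len(nd)) {
    best_j <- NA_integer_; best_d <- Inf
    for (j in seq_len(nt)) {
      if (used[j]) next
      dist <- sqrt(sum((cents[i, ] - truth[[j]]$center)^2))
      if (dist <= truth[[j]]$radius + slack && dist < best_d) {
        best_d <- dist; best_j <- j
      }
    }
    if (!is.na(best_j)) { matched[i] <- best_j; used[best_j] <- TRUE }
  }
  structure(list(TP = sum(!is.na(matched)), FP = sum(is.na(matched)),
                 FN = sum(!used), TN = NA_integer_, matched = matched),
            class = "aneuscan_confusion")
}

#' Confusion counts
#'
#' @param TP,FP,FN,TN non-negative integer counts; `TN` may be `NA` for
#'   detection tasks with no defined negative class.
#' @return List of class `aneuscan_confusion`.
#' @export
confusion_counts <- function(TP, FP, FN, TN = NA_integer_) {
  for (v in list(TP, FP, FN)) if (is.na(v) || v < 0) stop("counts must be >= 0")
  if (!is.na(TN) && TN < 0) stop("counts must be >= 0")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN), class = "aneuscan_confusion")
}

#' Detection metrics from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` (sensitivity),
#' `F1 = 2PR/(P+R)`, `FPR = FP/(FP+TN)`. A metric whose denominator is
#' zero (or whose counts are undefined) is reported as `NA`, not 0.
#'
#' @param counts an `aneuscan_confusion`.
#' @return List with `precision`, `recall`, `f1`, `fpr` as fractions.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "aneuscan_confusion"))
  p <- if (counts$TP + counts$FP > 0) counts$TP / (counts$TP + counts$FP) else NA_real_
  r <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  fpr <- if (!is.na(counts$TN) && counts$FP + counts$TN > 0)
    counts$FP / (counts$FP + counts$TN) else NA_real_
  list(precision = p, recall = r, f1 = f1, fpr = fpr)
}

#' F1 score from precision and recall
#'
#' Scale-invariant, so percentages in give percentages out.
#'
#' @param precision,recall values on a common scale.
#' @return `2 * P * R / (P + R)`.
#' @export
f1_score <- function(precision, recall) 2 * precision * recall / (precision + recall)

#' Precision-recall and ROC curves with AUC
#'
#' Sweeps the decision threshold over the unique score values (a score is
#' predicted positive iff it strictly exceeds the threshold, matching
#' [classify_target()]), producing a PR curve, a ROC curve and the area
#' under the ROC by the trapezoidal rule.
#'
#' @param scores numeric statistic per candidate (e.g. `V_mean`).
#' @param labels logical (or 0/1): is the candidate a true aneurysm.
#' @return List with `pr` and `roc` data.frames (threshold-sorted) and
#'   `auc`.
#' @export
pr_roc_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels sizes differ")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both a positive and a negative example are required")
  thr <- sort(unique(c(scores, min(scores) - 1)))
  rows <- lapply(thr, function(t) {
    pred <- scores > t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- n_pos - tp; tn <- n_neg - fp
    data.frame(threshold = t,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn),
               fpr = fp / (fp + tn))
  })
  curve <- do.call(rbind, rows)
  roc <- curve[order(curve$fpr, curve$recall), ]
  auc <- sum(diff(roc$fpr) * (head(roc$recall, -1) + tail(roc$recall, -1)) / 2)
  list(pr = curve[, c("threshold", "recall", "precision")],
       roc = curve[, c("threshold", "fpr", "recall")],
       auc = auc)
}
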