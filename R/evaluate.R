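#' Binary confusion counts
#'
#' @param truth,predicted 0/1 vectors of equal length (1 = peak).
#' @return list of class `binary_confusion` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  binary_confusion(tp = sum(truth == 1 & predicted == 1),
                   tn = sum(truth == 0 & predicted == 0),
                   fp = sum(truth == 0 & predicted == 1),
                   fn = sum(truth == 1 & predicted == 0))
}

#' @rdname confusion_counts
#' @param tp,tn,fp,fn Non-negative counts.
#' @export
binary_confusion <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "binary_confusion")
}

#' Classification metrics (as percentages)
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN); precision = TP / (TP + FP);
#' sensitivity = TP / (TP + FN); specificity = TN / (TN + FP); false positive
#' rate = FP / (FP + TN) = 100% - specificity. Each is returned as a
#' percentage. A metric whose denominator is zero is returned as NA (flagged
#' undefined), not propagated as NaN.
#'
#' @param cm A [binary_confusion()].
#' @return list with `accuracy`, `precision`, `sensitivity`, `specificity`,
#'   `fpr`, each in percent.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "binary_confusion"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("all-zero confusion matrix")
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(accuracy = div(cm$tp + cm$tn, total),
       precision = div(cm$tp, cm$tp + cm$fp),
       sensitivity = div(cm$tp, cm$tp + cm$fn),
       specificity = div(cm$tn, cm$tn + cm$fp),
       fpr = div(cm$fp, cm$fp + cm$tn))
}

#' ROC curve and AUC
#'
#' Sweeps the classification cutoff over all distinct predicted
#' probabilities, returning (FPR, TPR) points (monotone in FPR) and the area
#' under the curve by trapezoidal integration. Tied scores receive the usual
#' half credit, so the AUC equals the probability that a random peak scores
#' above a random artifact.
#'
#' @param probabilities Predicted probabilities.
#' @param labels True 0/1 labels; both classes required.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(probabilities, labels) {
  if (length(unique(labels)) < 2) stop("both classes required for ROC")
  thr <- sort(unique(probabilities), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = NA_real_, tpr = NA_real_)
  for (i in seq_len(nrow(pts))) {
    pred <- probabilities >= pts$threshold[i]
    pts$tpr[i] <- sum(pred & labels == 1) / n_pos
    pts$fpr[i] <- sum(pred & labels == 0) / n_neg
  }
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

ext_truth_levels <- c("artifact", "forward", "reverse", "unmatched")
ext_pred_levels <- c("artifact", "forward", "reverse", "unmatched", "missed")

#' Extended confusion matrix for event-level pipeline scoring
#'
#' Cross-tabulates ground-truth event labels against the pipeline's predicted
#' labels. Truth labels: artifact events are `artifact`; paired peaks take
#' their transit direction (`forward`/`reverse`); lone peaks are `unmatched`.
#' Each truth event is assigned the label of the nearest same-probe candidate
#' within `tolerance` samples (records labeled `coincident`, and candidates
#' the classifier rejected, count as predicted `artifact`); a truth peak with
#' no candidate was below the detection threshold and is `missed`. Candidates
#' with no nearby truth event are background noise and accrue to the
#' `artifact` truth row.
#'
#' @param truth A [ground_truth_events()] table.
#' @param records Match records from [run_matching()] or a pipeline run
#'   (columns `probe`, `sample_index`, `label`).
#' @param tolerance Truth-to-candidate association tolerance, samples.
#' @return A 4 x 5 integer matrix of class `extended_confusion` (rows: truth
#'   artifact/forward/reverse/unmatched; columns: predicted
#'   artifact/forward/reverse/unmatched/missed).
#' @export
extended_confusion <- function(truth, records, tolerance = 100L) {
  validate_events(truth)
  tab <- matrix(0L, 4, 5, dimnames = list(truth = ext_truth_levels,
                                          predicted = ext_pred_levels))
  pred_label <- ifelse(records$label == "coincident", "artifact",
                       records$label)
  used <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(truth))) {
    tl <- if (truth$kind[i] == "artifact") "artifact"
          else if (!is.na(truth$direction[i])) truth$direction[i]
          else "unmatched"
    cand <- which(records$probe == truth$probe[i] & !used)
    pl <- "missed"
    if (length(cand)) {
      d <- abs(records$sample_index[cand] - truth$sample_index[i])
      j <- which.min(d)
      if (d[j] <= tolerance) {
        pl <- pred_label[cand[j]]
        used[cand[j]] <- TRUE
      }
    }
    tab[tl, pl] <- tab[tl, pl] + 1L
  }
  # leftover candidates correspond to no simulated event: noise transients,
  # which are artifacts by definition
  for (i in which(!used))
    tab["artifact", pred_label[i]] <- tab["artifact", pred_label[i]] + 1L
  structure(tab, class = c("extended_confusion", class(tab)))
}

#' @export
print.extended_confusion <- function(x, ...) {
  y <- x
  attr(y, "class") <- NULL
  print(y)
  invisible(x)
}

#' Correct / incorrect match tally
#'
#' Correct matches: truth forward predicted forward plus truth reverse
#' predicted reverse. Incorrect matches: truth artifact or truth unmatched
#' events predicted forward or reverse.
#'
#' @param ext An [extended_confusion()] table.
#' @return list with `correct_matches` and `incorrect_matches`.
#' @export
tally_matches <- function(ext) {
  stopifnot(inherits(ext, "extended_confusion"))
  list(correct_matches = ext["forward", "forward"] + ext["reverse", "reverse"],
       incorrect_matches = sum(ext[c("artifact", "unmatched"),
                                   c("forward", "reverse")]))
}
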