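#' Confusion counts for synergy/antagonism calls
#'
#' The positive class is synergism: TP are correctly identified synergistic
#' combinations, TN correctly identified antagonistic ones. An indeterminate
#' call is never correct -- it counts against the true class (FN when the
#' label is synergism, FP when it is antagonism), keeping the evaluation
#' two-class without silently dropping pairs.
#'
#' @param calls Character vector of predictions
#'   (`synergism`/`antagonism`/`indeterminate`).
#' @param labels Character vector of true labels (`synergism`/`antagonism`),
#'   same length as `calls`, non-empty.
#' @return Object of class `confusion_counts`: list with integers `tp`, `tn`,
#'   `fp`, `fn` summing to the number of pairs.
#' @export
confusion <- function(calls, labels) {
  if (length(calls) != length(labels)) {
    stop("calls and labels must have the same length")
  }
  if (length(calls) == 0) stop("need at least one pair")
  stopifnot(all(labels %in% c("synergism", "antagonism")))
  syn <- labels == "synergism"
  structure(list(
    tp = sum(syn & calls == "synergism"),
    tn = sum(!syn & calls == "antagonism"),
    fp = sum(!syn & calls != "antagonism"),
    fn = sum(syn & calls != "synergism")
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP =", x$tp, " TN =", x$tn, " FP =", x$fp, " FN =", x$fn, "\n")
  invisible(x)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A `confusion_counts` object (or list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return Accuracy in [0, 1]; zero total pairs is an error.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("cannot compute accuracy over zero pairs")
  (counts$tp + counts$tn) / total
}

#' Area under the ROC curve
#'
#' Sweeps the decision threshold over the scores, computing the true- and
#' false-positive rates at each, and integrates TPR over FPR by the
#' trapezoidal rule; with ties handled by the sweep this equals the
#' Mann-Whitney concordance probability with ties counted 1/2. Synergism is
#' the positive class and larger scores rank more synergistic. Pairs with an
#' `NA` score are excluded first (with a warning).
#'
#' @param scores Numeric vector of ranking scores.
#' @param labels Character vector (`synergism`/`antagonism`), same length.
#' @return AUC in [0, 1], or `NA` (with a warning) if only one class is
#'   present after removing `NA` scores.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("synergism", "antagonism")))
  drop <- is.na(scores)
  if (any(drop)) {
    warning(sum(drop), " pair(s) with undefined score excluded from ROC")
    scores <- scores[!drop]
    labels <- labels[!drop]
  }
  pos <- labels == "synergism"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    warning("ROC-AUC undefined: only one class present")
    return(NA_real_)
  }
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1); a pair is called positive when its score is
#'   >= the threshold.
#' @export
roc_points <- function(scores, labels) {
  pos <- labels == "synergism"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(pos & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(!pos & scores >= t) / n_neg, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate predictions against labels
#'
#' Bundles the confusion counts, overall accuracy, per-class accuracies
#' (recall on synergistic and antagonistic pairs), and -- when ranking scores
#' are supplied -- the ROC-AUC.
#'
#' @param calls Character vector of predicted calls.
#' @param labels Character vector of true labels.
#' @param scores Optional numeric ranking scores for the ROC-AUC.
#' @return Object of class `evaluation_result`: list with `counts`,
#'   `accuracy`, `accuracy_synergy`, `accuracy_antagonism`, `auc` (`NA` when
#'   no scores given or undefined).
#' @export
evaluate_predictions <- function(calls, labels, scores = NULL) {
  counts <- confusion(calls, labels)
  acc_syn <- if (counts$tp + counts$fn > 0)
    counts$tp / (counts$tp + counts$fn) else NA_real_
  acc_ant <- if (counts$tn + counts$fp > 0)
    counts$tn / (counts$tn + counts$fp) else NA_real_
  auc <- if (is.null(scores)) NA_real_ else roc_auc(scores, labels)
  structure(list(counts = counts, accuracy = accuracy(counts),
                 accuracy_synergy = acc_syn, accuracy_antagonism = acc_ant,
                 auc = auc),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("accuracy %.3f (synergy %.3f / antagonism %.3f)",
              x$accuracy, x$accuracy_synergy, x$accuracy_antagonism))
  if (!is.na(x$auc)) cat(sprintf(", ROC-AUC %.3f", x$auc))
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Long format, columns `metric` and `value`.
#'
#' @param result An `evaluation_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path) {
  stopifnot(inherits(result, "evaluation_result"))
  out <- data.frame(
    metric = c("tp", "tn", "fp", "fn", "accuracy", "accuracy_synergy",
               "accuracy_antagonism", "roc_auc"),
    value = c(result$counts$tp, result$counts$tn, result$counts$fp,
              result$counts$fn, result$accuracy, result$accuracy_synergy,
              result$accuracy_antagonism, result$auc)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
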