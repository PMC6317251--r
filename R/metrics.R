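#' Confusion counts for a designated positive class
#'
#' @param predicted,truth Factors (or vectors coercible to character) of
#'   predicted and reference labels.
#' @param positive The label counted as positive.
#' @return A `confusion_counts` list with integers `TP`, `FP`, `FN`, `TN`;
#'   their sum equals the number of evaluated items.
#' @export
confusion_counts <- function(predicted, truth, positive = "LP") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  structure(list(
    TP = sum(predicted == positive & truth == positive),
    FP = sum(predicted == positive & truth != positive),
    FN = sum(predicted != positive & truth == positive),
    TN = sum(predicted != positive & truth != positive),
    positive = positive), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (positive = %s): TP %d, FP %d, FN %d, TN %d\n",
              x$positive, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Precision and recall from confusion counts
#'
#' Precision = TP / (TP + FP), recall (sensitivity) = TP / (TP + FN).
#'
#' @param counts A [confusion_counts()] object (or list with TP/FP/FN).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  if (counts$TP + counts$FP == 0)
    stop("undefined metric: precision has zero denominator (TP + FP = 0)")
  if (counts$TP + counts$FN == 0)
    stop("undefined metric: recall has zero denominator (TP + FN = 0)")
  c(precision = counts$TP / (counts$TP + counts$FP),
    recall = counts$TP / (counts$TP + counts$FN))
}

#' Macro-averaged F-score of the two patch classes
#'
#' Computes `P_nlp R_nlp / (P_nlp + R_nlp) + P_lp R_lp / (P_lp + R_lp)`,
#' which is algebraically the unweighted mean of the two per-class F1 scores;
#' it equals 1 for a perfect classifier and is symmetric under swapping the
#' class labels. (Each term is half the class F1 — the conventional factor 2
#' is absorbed by summing the two classes.)
#'
#' @param counts_lp Confusion counts with LP as the positive class.
#' @param counts_nlp Confusion counts with NLP as the positive class.
#' @return Scalar in `[0, 1]`.
#' @export
f_avg <- function(counts_lp, counts_nlp) {
  pr_lp <- precision_recall(counts_lp)
  pr_nlp <- precision_recall(counts_nlp)
  term <- function(pr) {
    if (pr[["precision"]] + pr[["recall"]] == 0) return(0)
    pr[["precision"]] * pr[["recall"]] / (pr[["precision"]] + pr[["recall"]])
  }
  term(pr_nlp) + term(pr_lp)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all distinct score values as thresholds (score >= threshold =>
#' positive), collects the (FPR, TPR) operating points, and integrates by
#' the trapezoidal rule. The resulting AUC equals the normalized
#' Mann-Whitney pairwise concordance.
#'
#' @param scores Numeric vector of positive-class scores.
#' @param labels Logical vector (or factor with positive class `LP`):
#'   `TRUE`/`LP` marks a positive.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels))
    labels <- as.character(labels) == "LP"
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("ROC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- c(diff(s) != 0, TRUE)      # one operating point per distinct score
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Full classification report for a validation set
#'
#' @param prob_lp Numeric vector of predicted LP probabilities.
#' @param truth Reference labels (factor with levels NLP/LP).
#' @return A `metric_report`: per-class precision/recall, `f_avg`, accuracy,
#'   `auc`, ROC points and both confusion count objects.
#' @export
classification_report <- function(prob_lp, truth) {
  truth <- as_lp_factor(truth)
  pred <- factor(ifelse(prob_lp > 0.5, "LP", "NLP"), levels = c("NLP", "LP"))
  c_lp <- confusion_counts(pred, truth, positive = "LP")
  c_nlp <- confusion_counts(pred, truth, positive = "NLP")
  pr_lp <- precision_recall(c_lp)
  pr_nlp <- precision_recall(c_nlp)
  roc <- roc_auc(prob_lp, truth == "LP")
  structure(list(
    precision_lp = pr_lp[["precision"]], recall_lp = pr_lp[["recall"]],
    precision_nlp = pr_nlp[["precision"]], recall_nlp = pr_nlp[["recall"]],
    f_avg = f_avg(c_lp, c_nlp),
    accuracy = mean(pred == truth),
    auc = roc$auc, roc_points = roc$points,
    confusion_lp = c_lp, confusion_nlp = c_nlp), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Patch classification: accuracy %.4f, F_avg %.4f, AUC %.4f\n",
              x$accuracy, x$f_avg, x$auc))
  cat(sprintf("  LP : precision %.4f, recall %.4f\n",
              x$precision_lp, x$recall_lp))
  cat(sprintf("  NLP: precision %.4f, recall %.4f\n",
              x$precision_nlp, x$recall_nlp))
  invisible(x)
}
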