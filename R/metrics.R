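#' Confusion counts from binary labels and predictions
#'
#' @param truth Binary vector of reference labels (0/1).
#' @param estimate Binary vector of predicted labels (0/1), same length.
#' @return A `confusion_counts` object: list with `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 1) {
    rlang::abort("truth and estimate must be equal-length, non-empty vectors",
                 class = "ssmfn_metric_error")
  }
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    rlang::abort("truth and estimate must be binary (0/1)",
                 class = "ssmfn_metric_error")
  }
  structure(list(
    tp = sum(truth == 1 & estimate == 1),
    tn = sum(truth == 0 & estimate == 0),
    fp = sum(truth == 0 & estimate == 1),
    fn = sum(truth == 1 & estimate == 0)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP =", x$tp, " TN =", x$tn,
      " FP =", x$fp, " FN =", x$fn, "\n")
  invisible(x)
}

as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(c)))
  structure(as.list(c[c("tp", "tn", "fp", "fn")]), class = "confusion_counts")
}

abort_undefined <- function(what) {
  rlang::abort(paste0(what, " is undefined for these counts"),
               class = "ssmfn_undefined_metric")
}

#' Accuracy: (TP + TN) / (TP + TN + FP + FN)
#' @param counts A [confusion_counts()] object (or compatible named list).
#' @return Accuracy in `[0, 1]`.
#' @export
metric_accuracy <- function(counts) {
  c <- as_counts(counts)
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) abort_undefined("accuracy")
  (c$tp + c$tn) / total
}

#' Sensitivity (recall, true-positive rate): TP / (TP + FN)
#' @inheritParams metric_accuracy
#' @return Sensitivity in `[0, 1]`; errors if no true positives exist in the
#'   reference (never silently 0).
#' @export
metric_sensitivity <- function(counts) {
  c <- as_counts(counts)
  if (c$tp + c$fn == 0) abort_undefined("sensitivity")
  c$tp / (c$tp + c$fn)
}

#' Specificity (true-negative rate): TN / (TN + FP)
#' @inheritParams metric_accuracy
#' @return Specificity in `[0, 1]`; errors if no true negatives exist in the
#'   reference.
#' @export
metric_specificity <- function(counts) {
  c <- as_counts(counts)
  if (c$tn + c$fp == 0) abort_undefined("specificity")
  c$tn / (c$tn + c$fp)
}

#' F1 score, in two forms
#'
#' `"standard"` is the conventional harmonic-mean F1,
#' `2 TP / (2 TP + FP + FN)`. `"threat"` is the threat-score (Jaccard) form
#' `TP / (TP + FP + FN)`, which some reports print under the F1 label. Both
#' are provided so either convention can be reproduced; every evaluation
#' report records which variant it used.
#'
#' @inheritParams metric_accuracy
#' @param variant `"standard"` (default) or `"threat"`.
#' @return The chosen score in `[0, 1]`.
#' @export
metric_f1 <- function(counts, variant = c("standard", "threat")) {
  variant <- match.arg(variant)
  c <- as_counts(counts)
  if (c$tp + c$fp + c$fn == 0) abort_undefined("F1")
  if (variant == "standard") {
    2 * c$tp / (2 * c$tp + c$fp + c$fn)
  } else {
    c$tp / (c$tp + c$fp + c$fn)
  }
}

#' Matthews correlation coefficient
#'
#' `((TP * TN) - (FP * FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`. When any marginal factor is zero (a degenerate predictor or a
#' single-class reference) the coefficient is returned as 0 by convention
#' rather than erroring, since degenerate predictors occur routinely early
#' in training.
#'
#' @inheritParams metric_accuracy
#' @return MCC in `[-1, 1]`.
#' @export
metric_mcc <- function(counts) {
  c <- as_counts(counts)
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)  # double: no overflow
  if (denom2 == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(denom2)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counted 1/2 — equal to
#' trapezoidal integration of the ROC curve. Computed from mean ranks, so it
#' is exact including ties.
#'
#' @param truth Binary labels (0/1), both classes present.
#' @param scores Real-valued scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))
#' @export
roc_auc <- function(truth, scores) {
  if (length(truth) != length(scores)) {
    rlang::abort("truth and scores must have equal length",
                 class = "ssmfn_metric_error")
  }
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) abort_undefined("AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full six-metric report from labels, predictions and scores
#'
#' The row format used throughout the experiment tables: accuracy, F1,
#' sensitivity, specificity, MCC and AUC, plus the confusion counts they were
#' computed from. Metrics whose preconditions fail (e.g. a single-class
#' reference) are reported as `NA`, never fabricated as 0 (MCC's documented
#' zero-denominator convention excepted).
#'
#' @param truth Binary labels.
#' @param estimate Binary predictions (hard labels).
#' @param scores Continuous positive-class scores for AUC (optional; `NA`
#'   AUC when absent).
#' @param f1_variant `"standard"` or `"threat"`; recorded in the report.
#' @return A one-row tibble: `acc`, `f1`, `f1_variant`, `sens`, `spec`,
#'   `mcc`, `auc`, `tp`, `tn`, `fp`, `fn`, `n`.
#' @export
metric_report <- function(truth, estimate, scores = NULL,
                          f1_variant = c("standard", "threat")) {
  f1_variant <- match.arg(f1_variant)
  counts <- confusion_counts(truth, estimate)
  safe <- function(expr) {
    tryCatch(expr, ssmfn_undefined_metric = function(e) NA_real_)
  }
  tibble::tibble(
    acc = safe(metric_accuracy(counts)),
    f1 = safe(metric_f1(counts, f1_variant)),
    f1_variant = f1_variant,
    sens = safe(metric_sensitivity(counts)),
    spec = safe(metric_specificity(counts)),
    mcc = metric_mcc(counts),
    auc = if (is.null(scores)) NA_real_ else safe(roc_auc(truth, scores)),
    tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    n = length(truth)
  )
}
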