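#' Confusion counts at a classification threshold
#'
#' A patient is predicted positive (NOC) iff their predicted probability is
#' greater than or equal to `t`; ties at the threshold classify positive.
#'
#' @param preds a `prediction_set`.
#' @param t threshold in \[0, 1\].
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `fp`, `tn`, `fn` and the `threshold` used.
#' @export
confusion_at_threshold <- function(preds, t) {
  stopifnot(t >= 0, t <= 1)
  pos <- preds$prob >= t
  lab <- preds$label == 1
  structure(list(tp = sum(pos & lab), fp = sum(pos & !lab),
                 tn = sum(!pos & !lab), fn = sum(!pos & lab),
                 threshold = t),
            class = "confusion_counts")
}

#' Threshold-based discrimination metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive and negative
#' predictive values, and the Youden index (sensitivity + specificity - 1).
#' Ratios with a zero denominator (e.g. PPV when nothing is predicted
#' positive) are returned as `NA`, flagged rather than fabricated.
#'
#' @param counts a `confusion_counts` object.
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden`.
#' @examples
#' # an all-negative classifier has sens 0, spec 1, youden 0
#' p <- structure(data.frame(prob = c(.1, .2), label = c(1, 0)),
#'                class = c("prediction_set", "data.frame"))
#' basic_metrics(confusion_at_threshold(p, 0.9))
#' @export
basic_metrics <- function(counts) {
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  spec <- ratio(counts$tn, counts$tn + counts$fp)
  c(sensitivity = sens, specificity = spec,
    ppv = ratio(counts$tp, counts$tp + counts$fp),
    npv = ratio(counts$tn, counts$tn + counts$fn),
    youden = sens + spec - 1)
}

#' Brier score of a prediction set
#'
#' Mean squared difference between predicted probability and binary outcome.
#' The constant predictor at the outcome prevalence pi scores pi(1 - pi) —
#' about 0.21 at 30% prevalence — which serves as the no-information
#' reference.
#'
#' @param preds a `prediction_set`.
#' @return A single number in \[0, 1\].
#' @export
brier_score <- function(preds) {
  stopifnot(nrow(preds) > 0)
  mean((preds$prob - preds$label)^2)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Over all (NOC, OC) patient pairs, the fraction in which the NOC patient
#' received the higher probability, counting ties as one half; equal to the
#' trapezoidal area under the empirical ROC curve. Computed via midranks, so
#' it is exact under ties and O(n log n).
#'
#' @param preds a `prediction_set` with both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(preds) {
  n1 <- sum(preds$label == 1)
  n0 <- sum(preds$label == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both outcome classes", call. = FALSE)
  r <- rank(preds$prob)  # midranks handle ties as 1/2
  (sum(r[preds$label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Choose a classification threshold for a prediction set
#'
#' Rules: `"youden"` (default) picks the threshold maximizing the Youden
#' index over the observed probabilities, taking the smallest such threshold
#' on ties; `"prevalence"` uses the outcome prevalence; `"fixed"` uses the
#' supplied value.
#'
#' @param preds a `prediction_set`.
#' @param rule one of `"youden"`, `"prevalence"`, `"fixed"`.
#' @param fixed threshold for `rule = "fixed"` (default 0.5).
#' @return A single threshold in \[0, 1\].
#' @export
choose_threshold <- function(preds, rule = c("youden", "prevalence", "fixed"),
                             fixed = 0.5) {
  rule <- match.arg(rule)
  if (rule == "fixed") return(fixed)
  if (rule == "prevalence") return(mean(preds$label))
  cand <- sort(unique(preds$prob))
  youden <- vapply(cand, function(t)
    basic_metrics(confusion_at_threshold(preds, t))[["youden"]], numeric(1))
  cand[which.max(youden)]  # which.max returns the first (smallest) maximizer
}

#' Full discrimination report for one model
#'
#' Assembles the seven-standard-metric panel — sensitivity, specificity,
#' Youden index, PPV, NPV, Brier score, AUC — at a threshold chosen by the
#' configured rule.
#'
#' @param preds a `prediction_set` with both classes present.
#' @param threshold_rule passed to [choose_threshold()].
#' @param fixed fixed threshold when `threshold_rule = "fixed"`.
#' @return An object of class `discrimination_report`: one-row data.frame
#'   with columns `model`, `threshold`, `sensitivity`, `specificity`,
#'   `youden`, `ppv`, `npv`, `brier`, `auc`.
#' @export
discrimination_report <- function(preds,
                                  threshold_rule = c("youden", "prevalence",
                                                     "fixed"),
                                  fixed = 0.5) {
  threshold_rule <- match.arg(threshold_rule)
  t <- choose_threshold(preds, threshold_rule, fixed)
  m <- basic_metrics(confusion_at_threshold(preds, t))
  structure(data.frame(model = unique(preds$model)[1], threshold = t,
                       sensitivity = m[["sensitivity"]],
                       specificity = m[["specificity"]],
                       youden = m[["youden"]], ppv = m[["ppv"]],
                       npv = m[["npv"]], brier = brier_score(preds),
                       auc = auc(preds), stringsAsFactors = FALSE),
            class = c("discrimination_report", "data.frame"))
}
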