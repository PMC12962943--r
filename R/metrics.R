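# Performance metrics: AUC, Youden threshold, confusion metrics,
# discrimination slope, decision curves.

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a random
#' positive scores above a random negative, ties counted half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (`MSI-H` positive).
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over the midpoints between
#' adjacent distinct scores (predicted positive means score >= threshold).
#' Ties in J break toward the higher threshold, i.e. higher specificity.
#' When all scores are equal the common value is returned (J = 0).
#'
#' @inheritParams roc_auc
#' @return The dichotomization threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- check_two_classes(labels)
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  cand <- (u[-length(u)] + u[-1]) / 2
  J <- vapply(cand, function(t) {
    mean(scores[y] >= t) + mean(scores[!y] < t) - 1
  }, numeric(1))
  best <- which(J >= max(J) - 1e-12)
  cand[max(best)]
}

#' Confusion metrics at a threshold
#'
#' Standard 2x2 metrics with predicted positive defined as score >=
#' threshold. A zero denominator (no predicted positives/negatives) yields
#' `NA`, not 0.
#'
#' @inheritParams roc_auc
#' @param threshold Dichotomization threshold.
#' @return One-row tibble with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- check_two_classes(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Discrimination slope
#'
#' Difference between the mean predicted score of the positive and negative
#' groups.
#'
#' @inheritParams roc_auc
#' @return Scalar slope.
#' @export
discrimination_slope <- function(scores, labels) {
  y <- check_two_classes(labels)
  mean(scores[y]) - mean(scores[!y])
}

#' Decision-curve analysis
#'
#' Net benefit `NB(t) = TP(t)/n - FP(t)/n * t/(1-t)` across a grid of
#' threshold probabilities, alongside the treat-all and treat-none reference
#' strategies.
#'
#' @inheritParams roc_auc
#' @param thresholds Threshold-probability grid in `(0, 1)`.
#' @return A `msirad_dca` tibble with `threshold`, `strategy`
#'   (`model` / `treat_all` / `treat_none`), and `net_benefit`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  y <- check_two_classes(labels)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_parameter("thresholds must lie in (0, 1)")
  }
  n <- length(y)
  prev <- mean(y)
  nb_model <- vapply(thresholds, function(t) {
    pred <- scores >= t
    sum(pred & y) / n - sum(pred & !y) / n * t / (1 - t)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- bind_rows(
    tibble(threshold = thresholds, strategy = "model", net_benefit = nb_model),
    tibble(threshold = thresholds, strategy = "treat_all", net_benefit = nb_all),
    tibble(threshold = thresholds, strategy = "treat_none", net_benefit = 0)
  )
  class(out) <- c("msirad_dca", class(out))
  out
}
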