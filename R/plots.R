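# ggplot2 visualizations: ROC curves, decision curves, score distributions.

#' @importFrom ggplot2 ggplot aes geom_line geom_abline geom_boxplot
#'   labs theme_minimal coord_cartesian facet_wrap autoplot
NULL

roc_points <- function(scores, labels) {
  y <- as_positive(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(
    fpr = vapply(thr, function(t) mean(scores[!y] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  )
}

#' Pooled ROC curves per model
#'
#' ROC curves of the out-of-fold scores pooled over repetitions, one curve
#' per model (TumRad, PancRad, IntRad), faceted by classifier when several
#' were run.
#'
#' @param cv A `msirad_cv`.
#' @return A ggplot object.
#' @export
plot_roc <- function(cv) {
  stopifnot(inherits(cv, "msirad_cv"))
  pts <- cv$scores |>
    group_by(classifier, model) |>
    dplyr::group_modify(~roc_points(.x$score, .x$label)) |>
    ungroup()
  p <- ggplot(pts, aes(x = fpr, y = tpr, colour = model)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(linewidth = 0.8) +
    labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
         title = "Pooled out-of-fold ROC") +
    theme_minimal()
  if (length(unique(pts$classifier)) > 1L) p <- p + facet_wrap(~classifier)
  p
}

#' Decision-curve plot
#'
#' Net benefit of the model against the treat-all and treat-none reference
#' strategies across threshold probabilities, with the clinically relevant
#' 10-70% band in view.
#'
#' @param dca A `msirad_dca` tibble from [decision_curve()], or a
#'   `msirad_cv` (the pooled IntRad scores of the first classifier are used).
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(dca) {
  if (inherits(dca, "msirad_cv")) {
    sc <- filter(dca$scores, model == "IntRad",
                 classifier == dca$config$classifiers[1])
    dca <- decision_curve(sc$score, sc$label)
  }
  prev <- max(dca$net_benefit[dca$strategy == "treat_all"])
  ggplot(dca, aes(x = threshold, y = net_benefit, colour = strategy)) +
    geom_line(linewidth = 0.8) +
    coord_cartesian(ylim = c(-0.05, prev * 1.2)) +
    labs(x = "Threshold probability", y = "Net benefit", colour = NULL,
         title = "Decision curve analysis") +
    theme_minimal()
}

#' Out-of-fold score distributions by class
#'
#' Box plots of the pooled out-of-fold risk scores per model, split by true
#' MSI status; the gap between group means is the discrimination slope.
#'
#' @param cv A `msirad_cv`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(cv) {
  stopifnot(inherits(cv, "msirad_cv"))
  sc <- mutate(cv$scores,
               status = ifelse(label, "MSI-H", "MSI-stable"))
  ggplot(sc, aes(x = status, y = score, fill = status)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~model) +
    labs(x = NULL, y = "Risk score", fill = NULL) +
    theme_minimal()
}

#' @method autoplot msirad_cv
#' @export
autoplot.msirad_cv <- function(object, type = c("roc", "dca", "scores"), ...) {
  type <- match.arg(type)
  switch(type,
    roc = plot_roc(object),
    dca = plot_decision_curve(object),
    scores = plot_score_distribution(object)
  )
}

#' @method autoplot msirad_dca
#' @export
autoplot.msirad_dca <- function(object, ...) plot_decision_curve(object)
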