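# Performance report and selection-frequency summaries.

#' Feature selection frequency across CV fits
#'
#' The fraction of (repetition x fold) fits in which each feature was
#' forward-selected, per region (and classifier), with the "frequently
#' selected" set defined by frequency strictly above `threshold` (the study
#' reports features selected more than 70% of the time).
#'
#' @param cv A `msirad_cv` from [run_repeated_cv()].
#' @param threshold Frequency cutoff for the top set (default 0.7).
#' @return Tibble with `classifier`, `region`, `feature`, `frequency`,
#'   `top`, sorted by decreasing frequency.
#' @export
selection_frequency <- function(cv, threshold = 0.7) {
  stopifnot(inherits(cv, "msirad_cv"))
  n_fits <- cv$config$n_repetitions * cv$config$k
  out <- summarise(
    group_by(cv$selection, classifier, region, feature),
    frequency = n() / n_fits, .groups = "drop"
  )
  out <- mutate(out, top = frequency > threshold)
  arrange(out, classifier, region, dplyr::desc(frequency))
}

#' Summarize a cross-validation run into a performance report
#'
#' Per model (TumRad, PancRad, IntRad) and classifier: the mean of each
#' per-repetition metric with 95% percentile intervals (2.5 and 97.5
#' percentiles across repetitions). Youden thresholds were fit per
#' repetition on the same pooled out-of-fold scores they evaluate; the
#' resulting threshold-selection optimism is inherent to the procedure and
#' recorded here rather than corrected.
#'
#' @param cv A `msirad_cv` with at least 2 repetitions.
#' @param threshold Selection-frequency cutoff passed to
#'   [selection_frequency()].
#' @return A `msirad_report`: list with `summary` (one row per model x
#'   classifier), `selection_frequency`, and `meta`.
#' @export
summarize_cv <- function(cv, threshold = 0.7) {
  stopifnot(inherits(cv, "msirad_cv"))
  if (cv$config$n_repetitions < 2L) {
    stop_parameter("need at least 2 repetitions to summarize")
  }
  lo <- function(x) quantile(x, 0.025, names = FALSE, na.rm = TRUE)
  hi <- function(x) quantile(x, 0.975, names = FALSE, na.rm = TRUE)
  summary <- summarise(
    group_by(cv$metrics, model, classifier),
    across(c(auc, sensitivity, specificity, ppv, npv, slope),
           list(mean = ~mean(.x, na.rm = TRUE), lo = lo, hi = hi)),
    .groups = "drop"
  )
  structure(
    list(
      summary = summary,
      selection_frequency = selection_frequency(cv, threshold),
      meta = list(
        n_repetitions = cv$config$n_repetitions, k = cv$config$k,
        interval = "percentile (2.5, 97.5) across repetitions",
        threshold_rule = "Youden, refit per repetition on pooled out-of-fold scores (optimistic)",
        frequency_threshold = threshold
      )
    ),
    class = "msirad_report"
  )
}

#' @export
print.msirad_report <- function(x, ...) {
  cat("<msirad_report> ", x$meta$n_repetitions, " repetitions, 95% ",
      x$meta$interval, "\n", sep = "")
  print(select(x$summary, model, classifier, auc_mean, auc_lo, auc_hi,
               sensitivity_mean, specificity_mean, npv_mean))
  top <- filter(x$selection_frequency, top)
  if (nrow(top) > 0L) {
    cat("\nFeatures selected > ", x$meta$frequency_threshold * 100, "% of fits:\n",
        sep = "")
    print(top)
  }
  invisible(x)
}

# broom-style accessors -------------------------------------------------------

#' Tidy a cross-validation result
#'
#' @param x A `msirad_cv`.
#' @param ... Unused.
#' @return The per-repetition metric tibble (repetition x model x
#'   classifier).
#' @method tidy msirad_cv
#' @export
tidy.msirad_cv <- function(x, ...) x$metrics

#' One-row summary of a cross-validation result
#'
#' @param x A `msirad_cv`.
#' @param ... Unused.
#' @return One-row tibble with the run dimensions and the mean IntRad AUC.
#' @method glance msirad_cv
#' @export
glance.msirad_cv <- function(x, ...) {
  m <- filter(x$metrics, model == "IntRad")
  tibble(
    n_cases = x$config$n_cases, n_positive = x$config$n_positive,
    n_repetitions = x$config$n_repetitions, k = x$config$k,
    n_classifiers = length(x$config$classifiers),
    mean_intrad_auc = mean(m$auc)
  )
}

#' Tidy a performance report
#'
#' @param x A `msirad_report`.
#' @param ... Unused.
#' @return The model x classifier summary tibble.
#' @method tidy msirad_report
#' @export
tidy.msirad_report <- function(x, ...) x$summary

#' One-row summary of a performance report
#'
#' @param x A `msirad_report`.
#' @param ... Unused.
#' @return One-row tibble with the best model/classifier by mean AUC.
#' @method glance msirad_report
#' @export
glance.msirad_report <- function(x, ...) {
  best <- x$summary[which.max(x$summary$auc_mean), ]
  tibble(
    best_model = best$model, best_classifier = best$classifier,
    best_auc = best$auc_mean,
    n_top_features = sum(x$selection_frequency$top)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
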