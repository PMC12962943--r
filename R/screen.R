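# Univariate Wilcoxon screening.

#' Wilcoxon rank-sum screening of features against MSI status
#'
#' Two-sided rank-sum test per feature with midrank tie handling: the exact
#' null distribution when both groups have at most 10 cases and there are no
#' ties, the normal approximation with tie correction otherwise. No
#' multiple-testing correction is applied; screening is descriptive and is
#' not part of the in-fold selection path. A constant feature gets p = 1 by
#' convention.
#'
#' @param table Feature tibble (`case_id` + feature columns).
#' @param labels Binary labels (`MSI-H` positive), aligned to rows.
#' @param alpha Significance level for the flag.
#' @return A tibble with `feature`, `p_value`, `significant`; the number of
#'   significant features is attached as the `n_significant` attribute.
#' @export
wilcoxon_screen <- function(table, labels, alpha = 0.05) {
  y <- check_two_classes(labels)
  feats <- setdiff(names(table), "case_id")
  use_exact <- sum(y) <= 10L && sum(!y) <= 10L
  p <- vapply(feats, function(f) {
    x <- table[[f]]
    if (length(unique(x)) == 1L) return(1)
    suppressWarnings(
      wilcox.test(x[y], x[!y], exact = use_exact, correct = TRUE)$p.value
    )
  }, numeric(1))
  out <- tibble(feature = feats, p_value = unname(p),
                significant = unname(p) < alpha)
  attr(out, "n_significant") <- sum(out$significant)
  out
}
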