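# Mutual information, mRMR ranking, and forward selection.

# Equal-frequency discretization by average ranks: invariant under strictly
# monotone transformations. Variables with few distinct values (e.g. binary
# labels) occupy correspondingly few bins.
rank_bins <- function(x, bins = 4L) {
  n <- length(x)
  b <- ceiling(rank(x, ties.method = "average") * bins / n)
  as.integer(pmin(pmax(b, 1L), bins))
}

mi_binned <- function(bx, by, bins = 4L) {
  n <- length(bx)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / n
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  ind <- as.vector(outer(px, py))
  pos <- joint > 0
  sum(joint[pos] * log2(joint[pos] / ind[pos]))
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Discretizes `x` (and `y`, if not already discrete) into `bins`
#' equal-frequency levels by average ranks and returns the plug-in mutual
#' information in bits. Rank-based binning makes the estimate invariant to
#' strictly monotone transformations of `x`; a degenerate `x` (single bin)
#' yields 0.
#'
#' @param x Numeric vector.
#' @param y Binary (or numeric) vector of the same length.
#' @param bins Number of discretization levels (default 4).
#' @return Nonnegative scalar, bits.
#' @export
mutual_information <- function(x, y, bins = 4L) {
  if (length(x) < 4L) stop_parameter("need at least 4 observations")
  if (length(x) != length(y)) stop_parameter("x and y lengths differ")
  if (is.logical(y) || is.factor(y) || is.character(y)) {
    y <- as.numeric(as_positive(y))
  }
  max(0, mi_binned(rank_bins(x, bins), rank_bins(y, bins), bins))
}

#' mRMR feature ranking (greedy MID scheme)
#'
#' Greedy minimum-redundancy maximum-relevance ranking with the difference
#' (MID) objective: the first pick maximizes relevance `MI(f, y)`; each
#' subsequent pick maximizes `MI(f, y) - mean(MI(f, s))` over the features
#' `s` already selected. Ties break deterministically toward the earlier
#' registry (column) position.
#'
#' @param table Feature tibble (`case_id` optional) or numeric matrix.
#' @param labels Binary labels aligned to rows.
#' @param k Number of features to rank.
#' @param bins Discretization levels for the MI estimates.
#' @return Character vector of `k` feature names in selection order.
#' @export
mrmr_rank <- function(table, labels, k, bins = 4L) {
  if (k <= 0L) stop_parameter("k must be positive")
  X <- as.matrix(table[setdiff(names(table), "case_id")])
  if (k > ncol(X)) stop_parameter("k exceeds the number of features")
  y <- as.numeric(check_two_classes(labels))
  B <- apply(X, 2L, rank_bins, bins = bins)
  by <- rank_bins(y, bins)
  p <- ncol(X)
  relevance <- vapply(seq_len(p), function(j) mi_binned(B[, j], by, bins),
                      numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance else relevance - red_sum / (step - 1L)
    score[selected] <- -Inf
    pick <- which.max(score)   # first index on ties = registry order
    selected <- c(selected, pick)
    if (step < k) {
      bp <- B[, pick]
      red_sum <- red_sum + vapply(seq_len(p), function(j) {
        mi_binned(B[, j], bp, bins)
      }, numeric(1))
    }
  }
  colnames(X)[selected]
}

#' Forward selection along an mRMR ranking
#'
#' Walks the ranked list in order and keeps a feature when adding it improves
#' the inner stratified 3-fold out-of-fold AUC on the training data by more
#' than `improvement`. The first ranked feature is always kept (the subset is
#' never empty); the walk stops at `cap` selected features.
#'
#' @param ranked Character vector of candidate features in mRMR order.
#' @param table Training feature tibble.
#' @param labels Training labels.
#' @param classifier One of `"logistic"`, `"svm"`, `"rf"`, `"xgb"`.
#' @param cap Maximum subset size (default 10).
#' @param seed Integer seed for the inner folds and classifier.
#' @param improvement Minimum AUC gain to accept a feature.
#' @return A `msirad_selection` list: `ranked`, `selected`, and the AUC
#'   trace `scores` (one entry per accepted feature).
#' @export
forward_select <- function(ranked, table, labels, classifier = "logistic",
                           cap = 10L, seed = 1L, improvement = 1e-3) {
  if (length(ranked) == 0L) stop_parameter("ranked feature list is empty")
  y <- check_two_classes(labels)
  X <- as.matrix(table[setdiff(names(table), "case_id")])
  folds <- inner_folds(y, k = 3L, seed = seed)
  selected <- character(0)
  trace <- numeric(0)
  best <- -Inf
  for (f in ranked) {
    if (length(selected) >= cap) break
    cand <- c(selected, f)
    auc <- inner_cv_auc(X[, cand, drop = FALSE], y, folds, classifier, seed)
    if (length(selected) == 0L || auc > best + improvement) {
      selected <- cand
      best <- auc
      trace <- c(trace, auc)
    }
  }
  structure(list(ranked = ranked, selected = selected, scores = trace),
            class = "msirad_selection")
}

# Stratified inner folds, re-derived (up to 5 times) if any training fold
# loses a class.
inner_folds <- function(y, k = 3L, seed = 1L) {
  for (try in 0:5) {
    folds <- stratified_folds(y, k = k, seed = derive_seed(seed, try))
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- y[folds != f]
      any(tr) && !all(tr)
    }, logical(1)))
    if (ok) return(folds)
  }
  stop_parameter("could not build inner folds with both classes in training")
}

# Pooled out-of-fold AUC of one classifier on a candidate feature matrix.
inner_cv_auc <- function(X, y, folds, classifier, seed) {
  scores <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- train_risk_model(classifier, X[tr, , drop = FALSE], y[tr],
                              seed = derive_seed(seed, f))
    scores[!tr] <- score_cases(model, X[!tr, , drop = FALSE])
  }
  roc_auc(scores, y)
}
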