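# Repeated stratified 3-fold cross-validation over TumRad, PancRad, IntRad.

#' Stratified fold assignment
#'
#' Class-wise shuffled round-robin assignment: per-class fold sizes differ by
#' at most 1, every case lands in exactly one fold. Deterministic given the
#' seed.
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per case.
#' @export
stratified_folds <- function(labels, k = 3L, seed = 1L) {
  y <- as_positive(labels)
  if (min(sum(y), sum(!y)) < k) {
    stop_parameter(paste0("each class needs at least k = ", k, " members"))
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Selection, training, and scoring for one outer fold
#'
#' The fold-level worker behind [run_repeated_cv()]. Per region (tumor,
#' pancreas): mRMR ranking and forward selection on the training cases only,
#' classifier training on the full training fold, and scoring of the test
#' fold. An inner stratified 3-fold split of the training cases produces
#' out-of-fold channel scores on which the logistic fusion (IntRad) model is
#' trained; the fused test score applies that combiner to the two test-fold
#' channel scores.
#'
#' Test labels are never used for selection, training, or scoring; the
#' optional `y_test` is only attached to the returned score table.
#'
#' @param tum_train,panc_train Training feature tibbles (aligned rows).
#' @param y_train Training labels.
#' @param tum_test,panc_test Test feature tibbles (aligned rows).
#' @param y_test Optional test labels, stored in the output for bookkeeping.
#' @param classifier Classifier kind for the region models.
#' @param mrmr_k Number of mRMR-ranked candidates fed to forward selection.
#' @param cap Forward-selection subset cap.
#' @param seed Integer seed.
#' @param improvement Forward-selection AUC gain threshold.
#' @return List with `scores` (tibble: `tumrad`, `pancrad`, `intrad`,
#'   `label`) and `selection` (tibble: `region`, `feature`, `rank`).
#' @export
crossval_fold <- function(tum_train, panc_train, y_train,
                          tum_test, panc_test, y_test = NULL,
                          classifier = "logistic", mrmr_k = 30L,
                          cap = 10L, seed = 1L, improvement = 1e-3) {
  y <- check_two_classes(y_train)
  regions <- list(tumor = list(tr = tum_train, te = tum_test),
                  pancreas = list(tr = panc_train, te = panc_test))
  test_scores <- list()
  oof_scores <- list()
  sel_rows <- list()
  inner <- inner_folds(y, k = 3L, seed = derive_seed(seed, 17L))
  for (ri in seq_along(regions)) {
    rname <- names(regions)[ri]
    Xtr <- as.matrix(regions[[ri]]$tr[setdiff(names(regions[[ri]]$tr), "case_id")])
    Xte <- as.matrix(regions[[ri]]$te[setdiff(names(regions[[ri]]$te), "case_id")])
    rseed <- derive_seed(seed, ri)
    k_use <- min(mrmr_k, ncol(Xtr))
    ranked <- mrmr_rank(as_tibble(Xtr), y, k = k_use)
    sel <- forward_select(ranked, as_tibble(Xtr), y, classifier,
                          cap = cap, seed = rseed, improvement = improvement)
    feats <- sel$selected
    model <- train_risk_model(classifier, Xtr[, feats, drop = FALSE], y,
                              seed = rseed)
    test_scores[[rname]] <- score_cases(model, Xte[, feats, drop = FALSE])
    # inner out-of-fold channel scores for fusion training
    oof <- numeric(length(y))
    for (f in sort(unique(inner))) {
      tr <- inner != f
      m_in <- train_risk_model(classifier, Xtr[tr, feats, drop = FALSE], y[tr],
                               seed = derive_seed(rseed, f))
      oof[!tr] <- score_cases(m_in, Xtr[!tr, feats, drop = FALSE])
    }
    oof_scores[[rname]] <- oof
    sel_rows[[rname]] <- tibble(region = rname, feature = feats,
                                rank = seq_along(feats))
  }
  fusion <- train_fusion(oof_scores$tumor, oof_scores$pancreas, y)
  intrad <- score_fusion(fusion, test_scores$tumor, test_scores$pancreas)
  n_te <- length(intrad)
  list(
    scores = tibble(
      tumrad = test_scores$tumor, pancrad = test_scores$pancreas,
      intrad = intrad,
      label = if (is.null(y_test)) rep(NA, n_te) else as_positive(y_test)
    ),
    selection = bind_rows(sel_rows)
  )
}

#' Repeated stratified 3-fold cross-validation
#'
#' The evaluation engine: for each repetition, a fresh stratified 3-fold
#' partition; within each fold, feature selection, model training, and
#' fusion are carried out on training data only ([crossval_fold()]), and the
#' held-out fold is scored. Per repetition, pooled out-of-fold scores yield
#' AUC, the Youden threshold, sensitivity/specificity/PPV/NPV at that
#' threshold, and the discrimination slope, per model (TumRad, PancRad,
#' IntRad) and classifier. All seeds derive deterministically from
#' `(seed, repetition, fold)`.
#'
#' @param tumor,pancreas Feature tibbles (`case_id` + 254 features), rows
#'   aligned with `labels`.
#' @param labels Binary cohort labels (`MSI-H` positive).
#' @param n_repetitions Number of CV repetitions (study setting 100; the
#'   desk-scale profile uses 10).
#' @param classifiers Character vector of classifier kinds to evaluate.
#' @param k Folds per repetition.
#' @param mrmr_k,cap,improvement Selection parameters (see
#'   [forward_select()]).
#' @param seed Master seed.
#' @return A `msirad_cv` object: list with `scores` (repetition x case x
#'   model x classifier out-of-fold scores), `selection` (per repetition x
#'   fold x region selected features), `metrics` (per repetition x model x
#'   classifier), and `config`.
#' @export
run_repeated_cv <- function(tumor, pancreas, labels, n_repetitions = 10L,
                            classifiers = "logistic", k = 3L, mrmr_k = 30L,
                            cap = 10L, improvement = 1e-3, seed = 1L) {
  stopifnot(nrow(tumor) == nrow(pancreas), nrow(tumor) == length(labels))
  if (!all(classifiers %in% classifier_kinds)) {
    stop_parameter("classifiers must be among logistic, svm, rf, xgb")
  }
  y <- check_two_classes(labels)
  case_ids <- if ("case_id" %in% names(tumor)) tumor$case_id else
    sprintf("case_%03d", seq_along(y))
  score_rows <- list()
  sel_rows <- list()
  metric_rows <- list()
  for (clf in classifiers) {
    for (rep_i in seq_len(n_repetitions)) {
      folds <- stratified_folds(y, k = k, seed = derive_seed(seed, rep_i))
      pooled <- matrix(NA_real_, length(y), 3L,
                       dimnames = list(NULL, c("TumRad", "PancRad", "IntRad")))
      for (f in seq_len(k)) {
        tr <- folds != f
        fold_out <- crossval_fold(
          tumor[tr, ], pancreas[tr, ], y[tr],
          tumor[!tr, ], pancreas[!tr, ], y[!tr],
          classifier = clf, mrmr_k = mrmr_k, cap = cap,
          seed = derive_seed(seed, rep_i, f), improvement = improvement
        )
        pooled[!tr, "TumRad"] <- fold_out$scores$tumrad
        pooled[!tr, "PancRad"] <- fold_out$scores$pancrad
        pooled[!tr, "IntRad"] <- fold_out$scores$intrad
        sel_rows[[length(sel_rows) + 1L]] <- mutate(
          fold_out$selection,
          classifier = clf, repetition = rep_i, fold = f
        )
      }
      for (model in colnames(pooled)) {
        s <- pooled[, model]
        thr <- youden_threshold(s, y)
        cm <- confusion_metrics(s, y, thr)
        metric_rows[[length(metric_rows) + 1L]] <- bind_cols(
          tibble(classifier = clf, repetition = rep_i, model = model,
                 auc = roc_auc(s, y), threshold = thr),
          cm,
          tibble(slope = discrimination_slope(s, y))
        )
      }
      score_rows[[length(score_rows) + 1L]] <- tibble(
        classifier = clf, repetition = rep_i,
        case_id = rep(case_ids, 3L),
        label = rep(y, 3L),
        model = rep(colnames(pooled), each = length(y)),
        score = as.vector(pooled)
      )
    }
  }
  structure(
    list(
      scores = bind_rows(score_rows),
      selection = bind_rows(sel_rows),
      metrics = bind_rows(metric_rows),
      config = list(n_repetitions = n_repetitions, k = k,
                    classifiers = classifiers, mrmr_k = mrmr_k, cap = cap,
                    improvement = improvement, seed = seed,
                    n_cases = length(y), n_positive = sum(y))
    ),
    class = "msirad_cv"
  )
}

#' @export
print.msirad_cv <- function(x, ...) {
  cat("<msirad_cv> ", x$config$n_repetitions, " repetitions x ",
      x$config$k, "-fold, ", x$config$n_cases, " cases (",
      x$config$n_positive, " MSI-H), classifiers: ",
      paste(x$config$classifiers, collapse = ", "), "\n", sep = "")
  m <- summarise(group_by(x$metrics, model, classifier),
                 mean_auc = mean(auc), .groups = "drop")
  print(m)
  invisible(x)
}
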