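# Folds, metrics, decision curves, and the CV engine on toy feature tables.

test_that("stratified folds reproduce the cohort's stratification arithmetic", {
  y <- c(rep(TRUE, 19), rep(FALSE, 76))
  f <- stratified_folds(y, k = 3, seed = 1)
  pos_sizes <- sort(table(f[y]), decreasing = TRUE)
  neg_sizes <- sort(table(f[!y]), decreasing = TRUE)
  expect_equal(as.integer(pos_sizes), c(7L, 6L, 6L))
  expect_equal(as.integer(neg_sizes), c(26L, 25L, 25L))
  expect_setequal(unique(f), 1:3)
  expect_length(f, 95L)

  f2 <- stratified_folds(y, k = 3, seed = 2)
  expect_false(identical(f, f2))
  expect_equal(sort(table(f2[y])), sort(table(f[y])))

  expect_error(stratified_folds(c(TRUE, TRUE, FALSE, FALSE), k = 3),
               class = "msirad_parameter_error")
})

test_that("AUC matches brute-force pair counting on random instances", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(s, y), brute_auc(s, y))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2), c(T, T, F, F, F)), 1)
  expect_equal(roc_auc(c(0.9, 0.5, 0.7, 0.3, 0.2), c(T, T, F, F, F)), 5 / 6)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("Youden threshold equals exhaustive midpoint search", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    s <- round(runif(n), 2)
    expect_equal(youden_threshold(s, y), brute_youden(s, y))
  }
  # separated scores reach J = 1 in the gap
  s <- c(0.8, 0.9, 0.1, 0.2, 0.7); y <- c(T, T, F, F, F)
  thr <- youden_threshold(s, y)
  expect_gt(thr, 0.7); expect_lte(thr, 0.8)
  cm <- confusion_metrics(s, y, thr)
  expect_equal(cm$sensitivity + cm$specificity - 1, 1)
  # all-equal scores: degenerate threshold, J = 0
  expect_equal(youden_threshold(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.3)
})

test_that("confusion metrics follow the 2x2 definitions and NA conventions", {
  s <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  cm <- confusion_metrics(s, y, 0.75)
  expect_equal(unlist(cm), c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))

  cm_lo <- confusion_metrics(s, y, 0)
  expect_equal(unlist(cm_lo[c("sensitivity", "specificity", "ppv")]),
               c(sensitivity = 1, specificity = 0, ppv = 0.4))
  expect_true(is.na(cm_lo$npv))

  cm_hi <- confusion_metrics(s, y, 2)
  expect_equal(unlist(cm_hi[c("sensitivity", "specificity", "npv")]),
               c(sensitivity = 0, specificity = 1, npv = 0.6))
  expect_true(is.na(cm_hi$ppv))
})

test_that("discrimination slope is the difference of group mean scores", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(discrimination_slope(c(0.6, 0.8, 0.4, 0.2), y), 0.4)
  expect_equal(discrimination_slope(c(1, 1, 0, 0), y), 1)
  expect_equal(discrimination_slope(c(0.5, 0.5, 0.5, 0.5), y), 0)
})

test_that("decision curves match the closed-form references", {
  y <- c(rep(TRUE, 4), rep(FALSE, 16))   # prevalence 0.2
  s <- c(rep(0.9, 4), rep(0.05, 16))     # perfect model
  dc <- decision_curve(s, y, thresholds = c(0.1, 0.3, 0.5))
  none <- dc$net_benefit[dc$strategy == "treat_none"]
  expect_true(all(none == 0))
  all01 <- dc$net_benefit[dc$strategy == "treat_all" & dc$threshold == 0.1]
  expect_equal(all01, 0.2 - 0.8 / 9)
  model_nb <- dc$net_benefit[dc$strategy == "model"]
  expect_equal(model_nb, rep(0.2, 3))    # NB = prevalence below every positive
  expect_error(decision_curve(s, y, thresholds = c(0, 0.5)),
               class = "msirad_parameter_error")
})

test_that("the CV engine produces a leak-free, reproducible result on toy tables", {
  toy <- toy_table(n = 36, p = 6, beta = 3, seed = 21)
  tum <- tibble::add_column(toy$table, case_id = sprintf("c%02d", 1:36), .before = 1)
  panc <- tum
  cv1 <- run_repeated_cv(tum, panc, toy$labels, n_repetitions = 3, seed = 5)
  cv2 <- run_repeated_cv(tum, panc, toy$labels, n_repetitions = 3, seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$metrics, cv2$metrics)

  # exactly one out-of-fold score per case per repetition per model
  counts <- dplyr::count(cv1$scores, repetition, model)
  expect_true(all(counts$n == 36))
  expect_true(all(is.finite(cv1$scores$score)))
  expect_gt(mean(cv1$metrics$auc[cv1$metrics$model == "IntRad"]), 0.8)
})

test_that("fold-level scores ignore test labels and score cases independently", {
  toy <- toy_table(n = 40, p = 5, beta = 3, seed = 31)
  tr <- 1:28; te <- 29:40
  out1 <- crossval_fold(toy$table[tr, ], toy$table[tr, ], toy$labels[tr],
                        toy$table[te, ], toy$table[te, ],
                        y_test = toy$labels[te], seed = 3)
  out2 <- crossval_fold(toy$table[tr, ], toy$table[tr, ], toy$labels[tr],
                        toy$table[te, ], toy$table[te, ],
                        y_test = !toy$labels[te], seed = 3)  # perturbed labels
  expect_identical(out1$scores[c("tumrad", "pancrad", "intrad")],
                   out2$scores[c("tumrad", "pancrad", "intrad")])

  # batch scoring equals case-by-case scoring
  single <- crossval_fold(toy$table[tr, ], toy$table[tr, ], toy$labels[tr],
                          toy$table[te[1], ], toy$table[te[1], ], seed = 3)
  expect_equal(single$scores$intrad, out1$scores$intrad[1])
})

test_that("selection frequency satisfies the counting identity and threshold filter", {
  toy <- toy_table(n = 36, p = 6, beta = 3, seed = 22)
  cv <- run_repeated_cv(toy$table, toy$table, toy$labels,
                        n_repetitions = 2, seed = 4)
  sf <- selection_frequency(cv, threshold = 0.7)
  n_fits <- cv$config$n_repetitions * cv$config$k
  for (r in c("tumor", "pancreas")) {
    freq <- sf$frequency[sf$region == r]
    mean_size <- nrow(cv$selection[cv$selection$region == r, ]) / n_fits
    expect_equal(sum(freq), mean_size)
  }
  expect_identical(sf$top, sf$frequency > 0.7)
  always <- selection_frequency(cv, threshold = 0)
  expect_true(all(always$frequency <= 1))
})

test_that("the report mirrors the model-by-classifier design", {
  toy <- toy_table(n = 36, p = 4, beta = 3, seed = 23)
  cv <- run_repeated_cv(toy$table, toy$table, toy$labels, n_repetitions = 2,
                        classifiers = c("logistic", "svm", "rf", "xgb"),
                        mrmr_k = 4, cap = 2, seed = 6)
  rep <- summarize_cv(cv)
  expect_equal(nrow(rep$summary), 12L)   # 3 models x 4 classifiers
  expect_setequal(unique(rep$summary$model), c("TumRad", "PancRad", "IntRad"))
  expect_true(all(rep$summary$auc_lo <= rep$summary$auc_mean + 1e-12))
  expect_true(all(rep$summary$auc_hi >= rep$summary$auc_mean - 1e-12))
  expect_true(all(rep$summary$sensitivity_mean >= 0 &
                    rep$summary$sensitivity_mean <= 1))

  # degenerate distribution: identical repetitions give width-0 intervals
  cvm <- cv
  cvm$metrics <- dplyr::mutate(cvm$metrics, auc = 0.75)
  repm <- summarize_cv(cvm)
  expect_true(all(repm$summary$auc_lo == 0.75 & repm$summary$auc_hi == 0.75))

  g <- glance(cv)
  expect_equal(g$n_cases, 36L)
  td <- tidy(cv)
  expect_true(all(c("repetition", "model", "auc") %in% names(td)))
})

test_that("plot helpers return ggplot objects", {
  toy <- toy_table(n = 36, p = 4, beta = 3, seed = 24)
  cv <- run_repeated_cv(toy$table, toy$table, toy$labels, n_repetitions = 2,
                        mrmr_k = 4, cap = 2, seed = 8)
  expect_s3_class(plot_roc(cv), "ggplot")
  expect_s3_class(plot_decision_curve(cv), "ggplot")
  expect_s3_class(plot_score_distribution(cv), "ggplot")
  sc <- dplyr::filter(cv$scores, model == "IntRad")
  expect_s3_class(ggplot2::autoplot(decision_curve(sc$score, sc$label)), "ggplot")
})
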