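# Wilcoxon screening, mutual information, mRMR, and forward selection.

test_that("the exact rank-sum p-value matches enumeration oracles", {
  tb <- tibble::tibble(f = c(1, 2, 3, 4, 5, 6))
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  out <- wilcoxon_screen(tb, y)
  expect_equal(out$p_value, 0.1)

  # identity case: both groups identical up to permutation
  tb2 <- tibble::tibble(f = c(1, 2, 3, 1, 2, 3))
  expect_equal(wilcoxon_screen(tb2, y)$p_value, 1)

  # perfect separation attains the most extreme p the design allows; the
  # heavy ties put this case on the normal-approximation path
  tb3 <- tibble::tibble(f = as.numeric(y))
  p_sep <- wilcoxon_screen(tb3, y)$p_value
  expect_gt(p_sep, 0)
  expect_lte(p_sep, 0.1)  # exact minimal two-sided p for a 3 vs 3 design
  shifted <- tibble::tibble(f = c(1, 2, 4, 3, 5, 6))
  expect_lt(p_sep, wilcoxon_screen(shifted, y)$p_value)
})

test_that("screening p-values match the permutation oracle on random samples", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n0 <- sample(3:8, 1)
    x <- c(rnorm(n1, mean = runif(1, 0, 2)), rnorm(n0))
    y <- c(rep(TRUE, n1), rep(FALSE, n0))
    p_pkg <- wilcoxon_screen(tibble::tibble(f = x), y)$p_value
    expect_lt(abs(p_pkg - perm_wilcoxon_p(x, y)), 0.01)
  }
})

test_that("constant features screen to p = 1 and flags match alpha", {
  tb <- tibble::tibble(flat = rep(2, 12), good = c(rep(0, 6), rep(1, 6)))
  y <- rep(c(TRUE, FALSE), each = 6)
  out <- wilcoxon_screen(tb, y)
  expect_equal(out$p_value[out$feature == "flat"], 1)
  expect_identical(out$significant, out$p_value < 0.05)
  expect_equal(attr(out, "n_significant"), sum(out$significant))
})

test_that("mutual information honors identity, independence, and monotone invariance", {
  y <- rep(c(TRUE, FALSE), 50)
  expect_equal(mutual_information(as.numeric(y), y), 1)

  set.seed(13)
  x <- rnorm(1000)
  yy <- rep(c(TRUE, FALSE), 500)
  expect_lt(mutual_information(x, yy), 0.05)

  x2 <- runif(60)
  y2 <- rep(c(TRUE, FALSE), 30)
  expect_equal(mutual_information(x2, y2), mutual_information(exp(3 * x2), y2))

  expect_equal(mutual_information(rep(1, 20), rep(c(TRUE, FALSE), 10)), 0)
})

test_that("greedy mRMR equals brute-force objective evaluation at every step", {
  set.seed(17)
  n <- 48
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  X[, 1] <- as.numeric(y) + rnorm(n, 0, 0.2)
  X[, 2] <- X[, 1]
  tb <- tibble::as_tibble(X)
  ranked <- mrmr_rank(tb, y, k = 12)

  # brute-force MID trace using the public MI estimator
  feats <- colnames(X)
  selected <- character(0)
  for (step in seq_len(12)) {
    cand <- setdiff(feats, selected)
    obj <- vapply(cand, function(f) {
      rel <- mutual_information(X[, f], y)
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(s) mutual_information(X[, f], X[, s]),
                    numeric(1)))
      rel - red
    }, numeric(1))
    best <- max(obj)
    pick <- cand[which(obj >= best - 1e-12)][1]  # registry-order tie-break
    selected <- c(selected, pick)
  }
  expect_identical(ranked, selected)
})

test_that("mRMR places a duplicate after an independent weak feature", {
  set.seed(19)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  f1 <- as.numeric(y) + rnorm(n, 0, 1e-3)
  f3 <- 0.4 * as.numeric(y) + rnorm(n)
  tb <- tibble::tibble(f1 = f1, f2 = f1, f3 = f3)
  expect_identical(mrmr_rank(tb, y, 3), c("f1", "f3", "f2"))
})

test_that("mRMR tie-break and base cases follow the contract", {
  y <- rep(c(TRUE, FALSE), 10)
  tb <- tibble::tibble(a = rep(1, 20), b = rep(1, 20), c = rep(1, 20))
  expect_identical(mrmr_rank(tb, y, 3), c("a", "b", "c"))
  toy <- toy_table()
  expect_identical(mrmr_rank(toy$table, toy$labels, 1), "f1")
  expect_error(mrmr_rank(toy$table, toy$labels, 0), class = "msirad_parameter_error")
})

test_that("forward selection stops when nothing improves and honors the cap", {
  toy <- toy_table(n = 60, beta = 5)
  ranked <- mrmr_rank(toy$table, toy$labels, 8)
  expect_identical(ranked[1], "f1")
  sel <- forward_select(ranked, toy$table, toy$labels, "logistic", seed = 2)
  expect_identical(sel$selected, "f1")  # perfect feature admits no gain

  sel1 <- forward_select(ranked, toy$table, toy$labels, "logistic",
                         cap = 1, seed = 2)
  expect_length(sel1$selected, 1L)

  noise <- toy_table(n = 40, beta = 0, seed = 5)
  seln <- forward_select(mrmr_rank(noise$table, noise$labels, 8),
                         noise$table, noise$labels, "logistic", seed = 3)
  expect_gte(length(seln$selected), 1L)
  expect_lte(length(seln$selected), 10L)
})

test_that("selection is a pure function of training data and seed", {
  toy <- toy_table(n = 50, beta = 1)
  ranked <- mrmr_rank(toy$table, toy$labels, 8)
  s1 <- forward_select(ranked, toy$table, toy$labels, "logistic", seed = 7)
  s2 <- forward_select(ranked, toy$table, toy$labels, "logistic", seed = 7)
  expect_identical(s1, s2)
})
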