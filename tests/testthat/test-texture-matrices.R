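# GLCM, histogram, and RLM features against hand-enumerated and brute-force
# oracles.

test_that("quantization follows the equal-width binning contract", {
  m <- matrix(0:31, 4, 8)
  q <- quantize_slice(m, matrix(TRUE, 4, 8), levels = 32)
  expect_equal(as.vector(q$q), 0:31)

  const <- quantize_slice(matrix(5, 3, 3), matrix(TRUE, 3, 3), 32)
  expect_true(all(const$q == 0))

  two <- quantize_slice(matrix(c(0, 10, 0, 10), 2, 2), matrix(TRUE, 2, 2), 2)
  expect_setequal(unique(as.vector(two$q)), c(0L, 1L))

  expect_error(quantize_slice(m, matrix(FALSE, 4, 8)), class = "msirad_region_error")
})

test_that("GLCM matches the hand-enumerated two-level example", {
  img <- matrix(rep(c(0, 0, 1, 1), each = 1), 4, 4, byrow = TRUE)
  img <- matrix(rep(c(0, 0, 1, 1), 4), 4, 4, byrow = TRUE)
  q <- quantize_slice(img, matrix(TRUE, 4, 4), levels = 2)
  P <- glcm(q, c(0, 1))
  expect_equal(P, matrix(c(1/3, 1/6, 1/6, 1/3), 2, 2))
  s <- glcm_stats(P)
  expect_equal(unname(s["energy"]), 5 / 18)
  expect_equal(unname(s["contrast"]), 1 / 3)
})

test_that("GLCM is normalized, symmetric, and degenerate on constant slices", {
  q <- quantize_slice(matrix(rnorm(64), 8, 8), matrix(TRUE, 8, 8), 8)
  P <- glcm(q, c(1, 0))
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))

  qc <- quantize_slice(matrix(1, 5, 5), matrix(TRUE, 5, 5), 16)
  Pc <- glcm(qc, c(0, 1))
  expect_equal(Pc[1, 1], 1)
  sc <- glcm_stats(Pc)
  expect_equal(unname(sc[c("energy", "contrast", "entropy")]), c(1, 0, 0))
})

test_that("gray-level reversal preserves energy and contrast", {
  set.seed(4)
  img <- matrix(runif(64), 8, 8)
  mask <- matrix(TRUE, 8, 8)
  q <- quantize_slice(img, mask, 8)
  qr <- q
  qr$q <- 7L - q$q
  for (d in c(0, 45, 90, 135)) {
    s1 <- glcm_stats(glcm(q, msirad:::direction_offset(d)))
    s2 <- glcm_stats(glcm(qr, msirad:::direction_offset(d)))
    expect_equal(s1[c("energy", "contrast")], s2[c("energy", "contrast")])
  }
})

test_that("GLCM pair counts match brute-force enumeration on random masked slices", {
  set.seed(11)
  for (i in 1:100) {
    img <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) > 0.3, 8, 8)
    if (sum(mask) < 2) next
    q <- quantize_slice(img, mask, 8)  # values already integer levels 0..3
    d <- sample(c(0, 45, 90, 135), 1)
    off <- msirad:::direction_offset(d)
    expect_equal(glcm(q, off), brute_glcm(q$q, mask, 8, off))
  }
})

test_that("histogram statistics match direct arithmetic and conventions", {
  s <- histogram_stats(c(1, 2, 3, 4))
  expect_equal(unname(s[c("mean", "range", "median")]), c(2.5, 3, 2.5))

  const <- histogram_stats(rep(7, 20))
  expect_equal(unname(const[c("sd", "skewness", "kurtosis", "entropy")]),
               c(0, 0, 0, 0))
  expect_equal(unname(const["energy"]), 1)

  expect_gt(unname(histogram_stats(c(1, 1, 1, 9))["skewness"]), 0)
  expect_error(histogram_stats(numeric(0)), class = "msirad_region_error")
})

test_that("RLM matches hand-enumerated constant and checkerboard slices", {
  qc <- quantize_slice(matrix(3, 4, 4), matrix(TRUE, 4, 4), 32)
  s <- rlm_features(qc, 0)
  expect_equal(unname(s[c("SRE", "LRE", "RP")]), c(1 / 16, 16, 4 / 16))

  chk <- (matrix(1:4, 4, 4) + matrix(1:4, 4, 4, byrow = TRUE)) %% 2
  qk <- quantize_slice(chk, matrix(TRUE, 4, 4), 2)
  sk <- rlm_features(qk, 0)
  expect_equal(unname(sk[c("SRE", "LRE", "RP")]), c(1, 1, 1))
})

test_that("SRE <= 1 and LRE >= 1 for arbitrary masked slices", {
  set.seed(21)
  for (i in 1:20) {
    img <- matrix(sample(0:2, 49, replace = TRUE), 7, 7)
    mask <- matrix(runif(49) > 0.2, 7, 7)
    if (sum(mask) < 2) next
    q <- quantize_slice(img, mask, 4)
    for (d in c(0, 45, 90, 135)) {
      s <- rlm_features(q, d)
      expect_lte(s[["SRE"]], 1)
      expect_gte(s[["LRE"]], 1)
    }
  }
})

test_that("RLM run counts match brute-force line walking on random masked slices", {
  set.seed(31)
  for (i in 1:100) {
    img <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) > 0.3, 8, 8)
    if (sum(mask) < 2) next
    q <- quantize_slice(img, mask, 4)
    d <- sample(c(0, 45, 90, 135), 1)
    runs <- brute_runs(q$q, mask, d)
    # compare summary statistics computed from the brute-force run list
    g <- runs[, 1] + 1; l <- runs[, 2]; nr <- nrow(runs)
    s <- rlm_features(q, d)
    expect_equal(s[["SRE"]], sum(1 / l^2) / nr)
    expect_equal(s[["LRE"]], sum(l^2) / nr)
    expect_equal(s[["RP"]], nr / sum(mask))
    expect_equal(s[["HGRE"]], sum(g^2) / nr)
  }
})
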