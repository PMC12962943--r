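# Shared fixtures, computed once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small cohort geometry used by unit tests (desk-scale, seconds to extract).
small_config <- function(effect_regions = c("tumor", "pancreas"),
                         sigma_case = 30, sigma_control = 10, seed = 42) {
  phantom_config(
    n_cases = 8, n_controls = 24, volume_shape = c(48L, 48L, 10L),
    pancreas_axes = c(18, 14, 3.5), tumor_axes = c(8, 6, 2),
    texture_sigma_case = sigma_case, texture_sigma_control = sigma_control,
    corr_length_case = 2, corr_length_control = 3,
    effect_regions = effect_regions, seed = seed
  )
}

tiny_config <- function(seed = 7) {
  phantom_config(
    n_cases = 3, n_controls = 6, volume_shape = c(32L, 32L, 6L),
    pancreas_axes = c(12, 9, 2.4), tumor_axes = c(5, 4, 1.6),
    corr_length_case = 1.5, corr_length_control = 2, seed = seed
  )
}

# Features of the small planted-effect cohort (reused by selection/CV tests).
small_features <- function() {
  cached("small_features", {
    coh <- generate_cohort_cases(small_config())
    list(
      tum = extract_features(coh$cases, "tumor"),
      panc = extract_features(coh$cases, "pancreas"),
      labels = coh$labels
    )
  })
}

# Full study-condition pipeline runs (19 + 76 cases, 64x64x12 volumes,
# 10 repetitions, logistic classifier) used by the acceptance tests.
study_pipeline <- function(effect = c("signal", "null")) {
  effect <- match.arg(effect)
  cached(paste0("study_", effect), {
    cfg <- if (effect == "null") {
      phantom_config(effect_regions = character(0), seed = 7)
    } else {
      phantom_config(seed = 7)
    }
    coh <- generate_cohort_cases(cfg)
    tum <- extract_features(coh$cases, "tumor")
    panc <- extract_features(coh$cases, "pancreas")
    cv <- run_repeated_cv(tum, panc, coh$labels, n_repetitions = 10L,
                          classifiers = "logistic", seed = 11)
    list(cv = cv, tum = tum, panc = panc, labels = coh$labels)
  })
}

# A small labelled feature table with a planted signal, no imaging involved.
toy_table <- function(n = 30, p = 8, beta = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(TRUE, FALSE), length.out = n)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    X[, 1] <- X[, 1] + beta * y
    list(table = tibble::as_tibble(X), labels = y)
  })
}
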