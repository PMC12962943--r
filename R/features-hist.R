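# Intensity-histogram features.

#' Intensity-histogram statistics
#'
#' First-order statistics of the raw in-mask intensities: mean, sd, skewness,
#' kurtosis, median, min, max, range, histogram energy and entropy (32
#' equal-width bins between the in-mask min and max), and the 10th/25th/75th/
#' 90th percentiles. A constant region has sd, skewness, kurtosis, and
#' entropy 0 by convention (its single-bin histogram has energy 1).
#'
#' @param values Numeric vector of in-mask intensities (length >= 1).
#' @param bins Number of histogram bins for energy/entropy.
#' @return Named numeric vector of 14 statistics.
#' @export
histogram_stats <- function(values, bins = 32L) {
  if (length(values) == 0L) stop_region("empty region")
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1L) sd(values) else 0
  m2 <- mean((values - m)^2)
  skew <- if (m2 < 1e-24) 0 else mean((values - m)^3) / m2^1.5
  kurt <- if (m2 < 1e-24) 0 else mean((values - m)^4) / m2^2
  rng <- range(values)
  if (rng[2] > rng[1]) {
    idx <- floor((values - rng[1]) / (rng[2] - rng[1]) * bins)
    idx[idx >= bins] <- bins - 1L
    p <- tabulate(idx + 1L, nbins = bins) / n
  } else {
    p <- c(1, rep(0, bins - 1L))
  }
  qs <- quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  c(
    mean = m, sd = s, skewness = skew, kurtosis = kurt,
    median = median(values), min = rng[1], max = rng[2],
    range = rng[2] - rng[1],
    energy = sum(p^2), entropy = entropy_bits(p),
    p10 = qs[1], p25 = qs[2], p75 = qs[3], p90 = qs[4]
  )
}
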