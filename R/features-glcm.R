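# Gray-level quantization and co-occurrence (Haralick) features.

#' Quantize a slice to discrete gray levels
#'
#' Equal-width binning of in-mask intensities into `levels` gray levels
#' between the in-mask minimum and maximum. A constant region maps entirely
#' to level 0. Out-of-mask pixels are `NA`.
#'
#' @param slice Numeric matrix of intensities.
#' @param mask Logical (or 0/1) matrix of the same shape.
#' @param levels Number of gray levels `L >= 2`.
#' @return A `quantized_slice`: list with `q` (integer matrix of levels in
#'   `[0, L-1]`, `NA` outside the mask), `levels`, and `range`.
#' @export
quantize_slice <- function(slice, mask, levels = 32L) {
  mask <- mask != 0
  if (!any(mask)) stop_region("mask is empty")
  if (levels < 2L) stop_parameter("levels must be >= 2")
  vals <- slice[mask]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(slice), ncol(slice))
  if (rng[2] == rng[1]) {
    q[mask] <- 0L
  } else {
    lev <- floor((vals - rng[1]) / (rng[2] - rng[1]) * levels)
    lev[lev >= levels] <- levels - 1L
    q[mask] <- as.integer(lev)
  }
  structure(list(q = q, levels = as.integer(levels), range = rng),
            class = "quantized_slice")
}

direction_offset <- function(direction) {
  switch(as.character(direction),
    "0" = c(0L, 1L),     # horizontal
    "45" = c(-1L, 1L),   # up-right
    "90" = c(1L, 0L),    # vertical
    "135" = c(1L, 1L),   # down-right
    stop_parameter("direction must be one of 0, 45, 90, 135")
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask gray-level pairs at a fixed pixel offset; both pixels of a
#' pair must lie inside the mask. The matrix is symmetrized (each pair
#' counted in both directions) and normalized to sum 1.
#'
#' @param q A `quantized_slice` from [quantize_slice()].
#' @param offset Integer `(dr, dc)` pixel offset (distance-1 directions are
#'   `c(0,1)`, `c(-1,1)`, `c(1,0)`, `c(1,1)`).
#' @return An `L x L` probability matrix, or `NULL` when the offset yields
#'   no valid in-mask pair (the slice is then skipped for this feature).
#' @export
glcm <- function(q, offset) {
  stopifnot(inherits(q, "quantized_slice"))
  L <- q$levels
  m <- q$q
  dr <- offset[1]; dc <- offset[2]
  nr <- nrow(m); nc <- ncol(m)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + dr >= 1L & rows + dr <= nr]
  c1 <- cols[cols + dc >= 1L & cols + dc <= nc]
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  a <- m[r1, c1, drop = FALSE]
  b <- m[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  counts <- tabulate(a[keep] * L + b[keep] + 1L, nbins = L * L)
  C <- matrix(counts, L, L, byrow = TRUE)   # row = level of first pixel
  C <- C + t(C)
  C / sum(C)
}

#' Haralick statistics of a co-occurrence matrix
#'
#' The classical 13-statistic set: energy, contrast, correlation, variance,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, and the two information
#' measures of correlation. Entropies are base-2 with `0 log 0 := 0`;
#' correlation of a degenerate (zero-variance) matrix is 0 by convention.
#'
#' @param P Normalized symmetric co-occurrence probability matrix.
#' @return Named numeric vector of 13 finite statistics.
#' @export
glcm_stats <- function(P) {
  L <- nrow(P)
  lev <- seq_len(L) - 1
  I <- matrix(lev, L, L)
  J <- t(I)
  px <- rowSums(P)                     # symmetric: px == py
  mu <- sum(lev * px)
  s2 <- sum((lev - mu)^2 * px)

  energy <- sum(P^2)
  contrast <- sum(P * (I - J)^2)
  correlation <- if (s2 < 1e-12) 0 else (sum(I * J * P) - mu^2) / s2
  variance <- s2
  idm <- sum(P / (1 + (I - J)^2))

  # p_{x+y}, k = 0 .. 2L-2
  ks <- 0:(2 * L - 2)
  pxy_sum <- vapply(ks, function(k) sum(P[I + J == k]), numeric(1))
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- entropy_bits(pxy_sum)

  # p_{|x-y|}, k = 0 .. L-1
  kd <- 0:(L - 1)
  pxy_diff <- vapply(kd, function(k) sum(P[abs(I - J) == k]), numeric(1))
  mu_d <- sum(kd * pxy_diff)
  difference_variance <- sum((kd - mu_d)^2 * pxy_diff)
  difference_entropy <- entropy_bits(pxy_diff)

  entropy <- entropy_bits(as.vector(P))
  hx <- entropy_bits(px)
  pp <- outer(px, px)
  pos <- pp > 0
  hxy1 <- -sum(P[pos] * log2(pp[pos]))
  hxy2 <- -sum(pp[pos] * log2(pp[pos]))
  imc1 <- if (hx < 1e-12) 0 else (entropy - hxy1) / hx
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(
    energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2
  )
}
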