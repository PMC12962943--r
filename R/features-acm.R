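# Angle co-occurrence matrix features (edge patterns).
#
# Gradient orientation is computed with 3x3 Sobel operators, folded to
# [0, 180) degrees, and quantized into 8 angle bins. Pixels whose gradient
# magnitude is zero or below a magnitude threshold (25th or 50th in-mask
# percentile) are excluded. An angle co-occurrence matrix is accumulated at
# offsets (0,1) and (1,0), symmetrized and normalized, and summarized by six
# co-occurrence statistics.

n_angle_bins <- 8L

sobel_gradients <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  gx <- matrix(NA_real_, nr, nc)
  gy <- matrix(NA_real_, nr, nc)
  if (nr < 3L || nc < 3L) return(list(gx = gx, gy = gy))
  r <- 2:(nr - 1L); c_ <- 2:(nc - 1L)
  s <- function(dr, dc) slice[r + dr, c_ + dc, drop = FALSE]
  gx[r, c_] <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
    (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy[r, c_] <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
    (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy)
}

cooc_stats <- function(P) {
  L <- nrow(P)
  I <- matrix(seq_len(L) - 1, L, L)
  J <- t(I)
  px <- rowSums(P)
  lev <- seq_len(L) - 1
  mu <- sum(lev * px)
  s2 <- sum((lev - mu)^2 * px)
  c(
    energy = sum(P^2),
    entropy = entropy_bits(as.vector(P)),
    contrast = sum(P * (I - J)^2),
    homogeneity = sum(P / (1 + abs(I - J))),
    correlation = if (s2 < 1e-12) 0 else (sum(I * J * P) - mu^2) / s2,
    dissimilarity = sum(P * abs(I - J))
  )
}

angle_cooccurrence <- function(bins, offset) {
  nr <- nrow(bins); nc <- ncol(bins)
  dr <- offset[1]; dc <- offset[2]
  rows <- seq_len(nr - max(dr, 0)); rows <- rows[rows + dr >= 1L]
  cols <- seq_len(nc - max(dc, 0)); cols <- cols[cols + dc >= 1L]
  a <- bins[rows, cols, drop = FALSE]
  b <- bins[rows + dr, cols + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  counts <- tabulate(a[keep] * n_angle_bins + b[keep] + 1L,
                     nbins = n_angle_bins^2)
  C <- matrix(counts, n_angle_bins, n_angle_bins, byrow = TRUE)
  C <- C + t(C)
  C / sum(C)
}

#' Angle co-occurrence matrix features
#'
#' 24 features: six co-occurrence statistics (energy, entropy, contrast,
#' homogeneity, correlation, dissimilarity) of the quantized-gradient-angle
#' co-occurrence matrix, for two offsets `(0,1)` and `(1,0)` and two
#' gradient-magnitude thresholds (25th and 50th in-mask percentiles).
#' Combinations with no above-threshold pixel pair return 0 (deterministic
#' convention).
#'
#' @param slice Numeric intensity matrix (values outside the mask provide
#'   gradient context at the mask border).
#' @param mask Logical (or 0/1) matrix.
#' @return Named numeric vector of 24 features.
#' @export
acm_features <- function(slice, mask) {
  mask <- mask != 0
  if (!any(mask)) stop_region("mask is empty")
  g <- sobel_gradients(slice)
  mag <- sqrt(g$gx^2 + g$gy^2)
  theta <- atan2(g$gy, g$gx) %% pi
  inmask <- mask & !is.na(mag)
  out <- numeric(0)
  mags <- mag[inmask]
  for (qp in c(0.25, 0.50)) {
    thr <- if (length(mags) > 0L) quantile(mags, qp, names = FALSE) else Inf
    keep <- inmask & mag >= thr & mag > 0
    bins <- matrix(NA_integer_, nrow(slice), ncol(slice))
    bins[keep] <- pmin(n_angle_bins - 1L,
                       floor(theta[keep] / (pi / n_angle_bins)))
    for (off in list(c(0L, 1L), c(1L, 0L))) {
      nm <- paste0(acm_stat_names, "_o", off[1], off[2], "_q", qp * 100)
      P <- angle_cooccurrence(bins, off)
      stats <- if (is.null(P)) setNames(rep(0, 6L), acm_stat_names) else cooc_stats(P)
      out <- c(out, setNames(stats, nm))
    }
  }
  out
}
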