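# Local binary pattern features.
#
# Three neighbourhood configurations (P=8,R=1; P=16,R=2; P=24,R=3) with
# rotation-invariant uniform (riu2) coding: a pixel's code is the number of
# neighbours >= center when the circular bit pattern has at most two 0/1
# transitions, and P+1 ("non-uniform") otherwise. Off-grid neighbour
# positions are sampled by bilinear interpolation; a pixel is eligible only
# when the full interpolation support of every neighbour lies inside the
# mask (erosion by the neighbourhood radius).

# Comparison tolerance: interpolation of equal values must compare as equal.
lbp_eps <- 1e-9

lbp_config_codes <- function(slice, mask, P, R) {
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr < 2 * R + 1 || nc < 2 * R + 1) return(NULL)
  rows <- (R + 1L):(nr - R)
  cols <- (R + 1L):(nc - R)
  center <- slice[rows, cols, drop = FALSE]
  elig <- mask[rows, cols, drop = FALSE]
  bits <- array(0L, dim = c(length(rows), length(cols), P))
  ang <- 2 * pi * (seq_len(P) - 1L) / P
  for (p in seq_len(P)) {
    dy <- round(-R * sin(ang[p]), 8)
    dx <- round(R * cos(ang[p]), 8)
    r0 <- floor(dy); c0 <- floor(dx)
    fr <- dy - r0; fc <- dx - c0
    r1 <- if (fr > 0) r0 + 1L else r0
    c1 <- if (fc > 0) c0 + 1L else c0
    # bilinear sample of the neighbour plane, via four constant shifts
    shift <- function(m, dr, dc) m[rows + dr, cols + dc, drop = FALSE]
    v <- (1 - fr) * (1 - fc) * shift(slice, r0, c0) +
      (1 - fr) * fc * shift(slice, r0, c1) +
      fr * (1 - fc) * shift(slice, r1, c0) +
      fr * fc * shift(slice, r1, c1)
    sup <- shift(mask, r0, c0)
    if (fc > 0) sup <- sup & shift(mask, r0, c1)
    if (fr > 0) sup <- sup & shift(mask, r1, c0)
    if (fr > 0 && fc > 0) sup <- sup & shift(mask, r1, c1)
    elig <- elig & sup
    scale <- pmax(1, abs(center))
    bits[, , p] <- (v >= center - lbp_eps * scale) + 0L
  }
  if (!any(elig)) return(NULL)
  bmat <- matrix(bits, ncol = P)[as.vector(elig), , drop = FALSE]
  transitions <- rowSums(bmat != bmat[, c(2:P, 1L), drop = FALSE])
  ones <- rowSums(bmat)
  ifelse(transitions <= 2L, ones, P + 1L)
}

#' Local binary pattern features
#'
#' 72 features: for each configuration (P=8,R=1), (P=16,R=2), (P=24,R=3),
#' the normalized riu2 code histogram (P+2 bins: 10, 18, 26) followed by six
#' histogram summaries (mean and sd of the code value, entropy, energy,
#' maximum bin, fraction of non-uniform patterns). Configurations whose
#' eroded mask is empty return `NA` (the slice is skipped for them during
#' averaging); if every configuration is ineligible a region error is raised.
#'
#' @param slice Numeric intensity matrix.
#' @param mask Logical (or 0/1) matrix.
#' @return Named numeric vector of 72 features.
#' @export
lbp_features <- function(slice, mask) {
  mask <- mask != 0
  if (!any(mask)) stop_region("mask is empty")
  out <- numeric(0)
  any_ok <- FALSE
  for (cfg in lbp_configs) {
    P <- cfg[["P"]]; R <- cfg[["R"]]
    codes <- lbp_config_codes(slice, mask, P, R)
    nm <- paste0("P", P, "R", R, "_",
                 c(paste0("bin", seq_len(P + 2L)), lbp_summary_names))
    if (is.null(codes)) {
      out <- c(out, setNames(rep(NA_real_, P + 8L), nm))
      next
    }
    any_ok <- TRUE
    hist <- tabulate(codes + 1L, nbins = P + 2L) / length(codes)
    vals <- 0:(P + 1L)
    mu <- sum(vals * hist)
    sdv <- sqrt(sum((vals - mu)^2 * hist))
    summ <- c(mu, sdv, entropy_bits(hist), sum(hist^2),
              max(hist), hist[P + 2L])
    out <- c(out, setNames(c(hist, summ), nm))
  }
  if (!any_ok) stop_region("eroded mask empty for every LBP configuration")
  out
}
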