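# Fractal-dimension features.
#
# For each of 16 equally spaced in-mask intensity thresholds, the slice is
# binarized (in-mask pixels >= threshold) and three estimators are computed:
# box-counting dimension of the set, box-counting dimension of its 4-connected
# boundary, and lacunarity (coefficient of variation of box masses at a fixed
# box size). Box grids are anchored at the mask bounding box, which makes the
# estimates translation-invariant.

n_fd_thresholds <- 16L
lacunarity_box <- 4L

# Box-counting dimension of a logical matrix (TRUE = foreground).
# Dyadic box sizes 1, 2, 4, ... up to half the larger matrix extent;
# slope of log2 N(s) on log2(1/s), clamped to [0, 2].
box_dimension <- function(bin) {
  if (!any(bin)) return(0)
  d <- max(dim(bin))
  kmax <- max(1L, floor(log2(d / 2)))
  sizes <- 2^(0:kmax)
  counts <- vapply(sizes, function(s) count_boxes(bin, s), numeric(1))
  fit <- lm(log2(counts) ~ I(log2(1 / sizes)))
  min(2, max(0, unname(coef(fit)[2])))
}

count_boxes <- function(bin, s) {
  br <- (row(bin) - 1L) %/% s
  bc <- (col(bin) - 1L) %/% s
  id <- br[bin] + bc[bin] * (max(br) + 1L)
  length(unique(id))
}

# 4-connected boundary: foreground pixels with at least one background or
# out-of-grid 4-neighbor.
boundary_pixels <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bin
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  bin & !interior
}

# Coefficient of variation of box masses over the full grid at a fixed scale.
lacunarity <- function(bin, s = lacunarity_box) {
  br <- (row(bin) - 1L) %/% s
  bc <- (col(bin) - 1L) %/% s
  id <- factor(br + bc * (max(br) + 1L))
  mass <- tapply(as.numeric(bin), id, sum)
  mu <- mean(mass)
  if (mu == 0) return(0)
  sd(mass) / mu
}

#' Fractal-dimension features
#'
#' 48 features: for 16 equally spaced in-mask intensity thresholds, the
#' box-counting dimension of the thresholded set (features 1-16), of its
#' boundary (17-32), and the lacunarity of the set at a fixed box scale
#' (33-48). An empty thresholded set yields 0 for its features
#' (deterministic convention).
#'
#' @param slice Numeric intensity matrix.
#' @param mask Logical (or 0/1) matrix.
#' @return Named numeric vector of 48 features, dimensions in `[0, 2]`.
#' @export
fd_features <- function(slice, mask) {
  mask <- mask != 0
  if (!any(mask)) stop_region("mask is empty")
  bb <- mask_bbox(mask)
  sl <- slice[bb$rows, bb$cols, drop = FALSE]
  mk <- mask[bb$rows, bb$cols, drop = FALSE]
  vals <- sl[mk]
  rng <- range(vals)
  thr <- rng[1] + seq_len(n_fd_thresholds) / (n_fd_thresholds + 1) * (rng[2] - rng[1])
  set_dim <- bnd_dim <- lac <- numeric(n_fd_thresholds)
  for (k in seq_len(n_fd_thresholds)) {
    bin <- mk & (sl >= thr[k])
    if (!any(bin)) next   # all three stay 0
    set_dim[k] <- box_dimension(bin)
    bnd <- boundary_pixels(bin)
    bnd_dim[k] <- if (any(bnd)) box_dimension(bnd) else 0
    lac[k] <- lacunarity(bin)
  }
  setNames(
    c(set_dim, bnd_dim, lac),
    c(paste0("set_dim_thr", seq_len(n_fd_thresholds)),
      paste0("bnd_dim_thr", seq_len(n_fd_thresholds)),
      paste0("lacunarity_thr", seq_len(n_fd_thresholds)))
  )
}
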