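# Run-length matrix features.

# Collect (level, run length) pairs over maximal in-mask collinear
# constant-level segments of one line (vector with NA outside the mask).
line_runs <- function(line) {
  idx <- which(!is.na(line))
  if (length(idx) == 0L) return(NULL)
  seg <- cumsum(c(1L, diff(idx) != 1L))
  out <- lapply(split(line[idx], seg), function(v) {
    r <- rle(v)
    cbind(level = r$values, len = r$lengths)
  })
  do.call(rbind, out)
}

# All lines of a matrix along one of the four run directions.
direction_lines <- function(m, direction) {
  switch(as.character(direction),
    "0" = lapply(seq_len(nrow(m)), function(r) m[r, ]),
    "90" = lapply(seq_len(ncol(m)), function(c_) m[, c_]),
    # 45 deg: anti-diagonals (r + c constant); 135 deg: diagonals (r - c constant)
    "45" = {
      s <- row(m) + col(m)
      lapply(split(m[order(s, -row(m))], sort(as.vector(s))), identity)
    },
    "135" = {
      d <- row(m) - col(m)
      lapply(split(m[order(d, row(m))], sort(as.vector(d))), identity)
    },
    stop_parameter("direction must be one of 0, 45, 90, 135")
  )
}

#' Run-length matrix features
#'
#' Eleven classical run-length statistics (SRE, LRE, GLN, RLN, RP, LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE) for one run direction. Runs are maximal
#' in-mask collinear constant-level segments; gray-level weighting uses
#' 1-based level indices. `RP` is the number of runs divided by the number of
#' in-mask pixels.
#'
#' @param q A `quantized_slice` from [quantize_slice()].
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @return Named numeric vector of 11 statistics.
#' @export
rlm_features <- function(q, direction = 0) {
  stopifnot(inherits(q, "quantized_slice"))
  m <- q$q
  np <- sum(!is.na(m))
  if (np == 0L) stop_region("empty region")
  runs <- do.call(rbind, lapply(direction_lines(m, direction), line_runs))
  g <- runs[, "level"] + 1   # 1-based gray level
  l <- runs[, "len"]
  nr <- nrow(runs)

  gl_counts <- tapply(rep(1, nr), g, sum)
  rl_counts <- tapply(rep(1, nr), l, sum)

  c(
    SRE = sum(1 / l^2) / nr,
    LRE = sum(l^2) / nr,
    GLN = sum(gl_counts^2) / nr,
    RLN = sum(rl_counts^2) / nr,
    RP = nr / np,
    LGRE = sum(1 / g^2) / nr,
    HGRE = sum(g^2) / nr,
    SRLGE = sum(1 / (g^2 * l^2)) / nr,
    SRHGE = sum(g^2 / l^2) / nr,
    LRLGE = sum(l^2 / g^2) / nr,
    LRHGE = sum(g^2 * l^2) / nr
  )
}
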