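#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols n across row_number
#' @importFrom stats median quantile sd rnorm glm binomial plogis predict
#'   wilcox.test lm coef cor setNames
#' @importFrom utils head tail
NULL

# Classed error helpers -------------------------------------------------------

stop_parameter <- function(msg) abort(msg, class = "msirad_parameter_error")
stop_region    <- function(msg) abort(msg, class = "msirad_region_error")
stop_geometry  <- function(msg) abort(msg, class = "msirad_geometry_error")
stop_format    <- function(msg) abort(msg, class = "msirad_format_error")
stop_schema    <- function(msg) abort(msg, class = "msirad_schema_error")

# Deterministic seed stream ---------------------------------------------------

# Fold an arbitrary tuple of small integers into a single 31-bit seed.
# Pure arithmetic (doubles stay < 2^53), so streams derived from one master
# seed are reproducible across platforms.
derive_seed <- function(...) {
  ints <- c(...)
  x <- 104729
  for (i in ints) {
    x <- (x * 69069 + abs(as.numeric(i)) + 1) %% 2147483647
  }
  as.integer(x)
}

# Coerce labels to logical with MSI-H as the positive class.
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "MSI-H"
}

check_two_classes <- function(y) {
  y <- as_positive(y)
  if (all(y) || !any(y)) stop_parameter("both classes must be present")
  y
}

# Bounding box of a logical mask with a clamped margin.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_region("mask is empty")
  list(
    rows = max(1L, min(idx[, 1]) - margin):min(nrow(mask), max(idx[, 1]) + margin),
    cols = max(1L, min(idx[, 2]) - margin):min(ncol(mask), max(idx[, 2]) + margin)
  )
}

# Shannon entropy (bits) of a probability vector, 0 log 0 := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}
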