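# The 254-feature texture registry.
#
# Families and counts: GLCM 52 (13 Haralick statistics x 4 directions at
# distance 1), HIST 14 (intensity-histogram statistics), RLM 44 (11 run-length
# statistics x 4 directions), FD 48 (16 intensity thresholds x 3 fractal
# estimators), LBP 72 (rotation-invariant uniform histograms for three
# (P, R) configurations plus per-configuration summaries), ACM 24 (6 angle
# co-occurrence statistics x 2 offsets x 2 gradient-magnitude thresholds).

glcm_stat_names <- c(
  "energy", "contrast", "correlation", "variance", "idm",
  "sum_average", "sum_variance", "sum_entropy", "entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2"
)

hist_stat_names <- c(
  "mean", "sd", "skewness", "kurtosis", "median", "min", "max", "range",
  "energy", "entropy", "p10", "p25", "p75", "p90"
)

rlm_stat_names <- c(
  "SRE", "LRE", "GLN", "RLN", "RP",
  "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE"
)

acm_stat_names <- c(
  "energy", "entropy", "contrast", "homogeneity", "correlation", "dissimilarity"
)

texture_directions <- c(0L, 45L, 90L, 135L)

# (P, R) neighbourhood configurations for local binary patterns.
lbp_configs <- list(c(P = 8L, R = 1L), c(P = 16L, R = 2L), c(P = 24L, R = 3L))

lbp_summary_names <- c(
  "mean", "sd", "entropy", "energy", "max_bin", "frac_nonuniform"
)

#' Texture feature registry
#'
#' The ordered inventory of the 254 radiomic texture features computed per
#' region. Feature names are `family + index` (e.g. `FD31`, `RLM11`, `LBP72`);
#' the `description` column records the parameterization behind each index.
#'
#' @return A tibble with one row per feature and columns `name`, `family`,
#'   `index`, and `description`, in extraction order (GLCM, HIST, RLM, FD,
#'   LBP, ACM).
#' @examples
#' reg <- feature_registry()
#' nrow(reg)            # 254
#' table(reg$family)
#' @export
feature_registry <- function() {
  glcm <- tibble(
    family = "GLCM",
    description = as.vector(t(outer(
      texture_directions, glcm_stat_names,
      function(d, s) paste0(s, "_d", d)
    )))
  )
  hist <- tibble(family = "HIST", description = hist_stat_names)
  rlm <- tibble(
    family = "RLM",
    description = as.vector(t(outer(
      texture_directions, rlm_stat_names,
      function(d, s) paste0(s, "_d", d)
    )))
  )
  fd <- tibble(
    family = "FD",
    description = c(
      paste0("set_dimension_thr", 1:16),
      paste0("boundary_dimension_thr", 1:16),
      paste0("lacunarity_thr", 1:16)
    )
  )
  lbp <- tibble(
    family = "LBP",
    description = unlist(lapply(lbp_configs, function(cfg) {
      p <- cfg[["P"]]
      c(
        paste0("P", p, "R", cfg[["R"]], "_bin", seq_len(p + 2L)),
        paste0("P", p, "R", cfg[["R"]], "_", lbp_summary_names)
      )
    }))
  )
  acm <- tibble(
    family = "ACM",
    description = as.vector(outer(
      acm_stat_names,
      c("o01_q25", "o10_q25", "o01_q50", "o10_q50"),
      function(s, o) paste0(s, "_", o)
    ))
  )
  reg <- bind_rows(glcm, hist, rlm, fd, lbp, acm)
  reg <- mutate(
    group_by(reg, family),
    index = row_number()
  )
  reg <- ungroup(reg)
  reg <- mutate(reg, name = paste0(family, index))
  select(reg, name, family, index, description)
}

registry_names <- function(registry = feature_registry()) registry$name
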