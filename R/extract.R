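# Slice-wise feature extraction and slice averaging.

#' Extract the 254-feature vector for one region of one case
#'
#' Every feature is computed on each eligible axial slice (at least
#' `min_pixels` in-mask pixels) and averaged, unweighted, over the slices on
#' which it is defined; slices failing a feature's own precondition (e.g. no
#' valid co-occurrence pair at an offset, empty eroded LBP mask) are skipped
#' for that feature only. Slices are cropped to the mask bounding box (plus a
#' small gradient-context margin), which makes all features invariant to
#' translating the mask and image content within the grid.
#'
#' @param case A `volume_case`.
#' @param region `"tumor"` or `"pancreas"`.
#' @param registry Feature registry (defaults to [feature_registry()]).
#' @param levels Gray levels for quantization-based families.
#' @param min_pixels Slice eligibility floor (in-mask pixel count).
#' @return Named numeric vector of 254 finite features in registry order.
#' @export
extract_region_features <- function(case, region = c("tumor", "pancreas"),
                                    registry = feature_registry(),
                                    levels = 32L, min_pixels = 16L) {
  region <- match.arg(region)
  mask3 <- if (region == "tumor") case$tumor_mask else case$pancreas_mask
  vol <- case$intensities
  nz <- dim(vol)[3]
  eligible <- which(vapply(seq_len(nz), function(z) sum(mask3[, , z] != 0),
                           numeric(1)) >= min_pixels)
  if (length(eligible) == 0L) {
    stop_region(paste0("no eligible ", region, " slice (>= ", min_pixels,
                       " in-mask pixels) for case ", case$case_id))
  }
  per_slice <- lapply(eligible, function(z) {
    slice_features(vol[, , z], mask3[, , z] != 0, levels = levels)
  })
  mat <- do.call(rbind, per_slice)
  avg <- colMeans(mat, na.rm = TRUE)
  bad <- !is.finite(avg)
  if (any(bad)) {
    stop_region(paste0("feature(s) undefined on every eligible slice for case ",
                       case$case_id, ": ",
                       paste(head(registry$name[bad], 5L), collapse = ", ")))
  }
  setNames(avg, registry$name)
}

# All 254 features of a single masked slice, ordered GLCM, HIST, RLM, FD,
# LBP, ACM to match the registry. NA marks a feature whose precondition
# failed on this slice.
slice_features <- function(slice, mask, levels = 32L) {
  bb <- mask_bbox(mask, margin = 3L)
  sl <- slice[bb$rows, bb$cols, drop = FALSE]
  mk <- mask[bb$rows, bb$cols, drop = FALSE]
  vals <- sl[mk]
  q <- quantize_slice(sl, mk, levels)

  glcm_f <- unlist(lapply(texture_directions, function(d) {
    P <- glcm(q, direction_offset(d))
    if (is.null(P)) rep(NA_real_, 13L) else glcm_stats(P)
  }))
  hist_f <- histogram_stats(vals)
  rlm_f <- unlist(lapply(texture_directions, function(d) rlm_features(q, d)))
  fd_f <- fd_features(sl, mk)
  lbp_f <- tryCatch(lbp_features(sl, mk),
                    msirad_region_error = function(e) rep(NA_real_, 72L))
  acm_f <- acm_features(sl, mk)
  unname(c(glcm_f, hist_f, rlm_f, fd_f, lbp_f, acm_f))
}

#' Extract a feature table for a cohort
#'
#' Runs [extract_region_features()] for every case and assembles the
#' patients-by-features table for one region. Accepts either a manifest
#' tibble (cases are loaded from the referenced NIfTI files) or a list of
#' in-memory `volume_case` objects.
#'
#' @param cohort A manifest tibble from [read_manifest()] /
#'   [generate_cohort()], or a list of `volume_case` objects.
#' @param region `"tumor"` or `"pancreas"`.
#' @inheritParams extract_region_features
#' @return A tibble with `case_id` and the 254 registry feature columns, in
#'   cohort order; the region name is attached as the `region` attribute.
#' @export
extract_features <- function(cohort, region = c("tumor", "pancreas"),
                             registry = feature_registry(),
                             levels = 32L, min_pixels = 16L) {
  region <- match.arg(region)
  cases <- if (is.data.frame(cohort)) {
    lapply(seq_len(nrow(cohort)), function(i) load_case(cohort[i, ]))
  } else {
    cohort
  }
  rows <- lapply(cases, function(vc) {
    fv <- extract_region_features(vc, region, registry, levels, min_pixels)
    bind_cols(tibble(case_id = vc$case_id), as_tibble(as.list(fv)))
  })
  out <- bind_rows(rows)
  attr(out, "region") <- region
  out
}
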