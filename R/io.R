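# Cohort and feature-table I/O.

manifest_columns <- c("case_id", "label", "volume", "tumor_mask", "pancreas_mask")

#' Read and validate a cohort manifest
#'
#' @param path CSV file with columns
#'   `case_id,label,volume,tumor_mask,pancreas_mask`. Labels must be `MSI-H`
#'   (positive class) or `control`.
#' @return A tibble with `label` as a factor (levels `control`, `MSI-H`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format(paste0("manifest not found: ", path))
  m <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop_format(paste0("cannot parse manifest: ", conditionMessage(e)))
  )
  if (nrow(m) == 0L) stop_format("manifest is empty")
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing) > 0L) {
    stop_format(paste0("manifest missing column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- m$case_id[duplicated(m$case_id)]
  if (length(dup) > 0L) {
    stop_format(paste0("duplicate case_id in manifest: ", paste(unique(dup), collapse = ", ")))
  }
  bad <- !m$label %in% c("MSI-H", "control")
  if (any(bad)) {
    stop_format(paste0(
      "unknown label for case(s) ",
      paste(m$case_id[bad], collapse = ", "),
      " (expected 'MSI-H' or 'control')"
    ))
  }
  m$label <- factor(m$label, levels = c("control", "MSI-H"))
  as_tibble(m[manifest_columns])
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path), class = "msirad_io_error")
  arr <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(paste0("cannot read ", path, ": ",
                                                   conditionMessage(e)),
                                            class = "msirad_io_error"))
  a <- as.array(arr)
  attributes(a) <- list(dim = dim(a))
  a
}

binarize_mask <- function(arr, path) {
  vals <- unique(as.vector(arr))
  nz <- vals[vals != 0]
  if (length(nz) > 1L) {
    stop_format(paste0("multi-label mask not supported: ", path,
                       " (values ", paste(sort(nz), collapse = ", "), ")"))
  }
  out <- array(as.integer(arr != 0), dim = dim(arr))
  if (sum(out) == 0L) stop_geometry(paste0("mask has no foreground voxels: ", path))
  out
}

#' Load one case from a manifest row
#'
#' Reads the volume and both masks, binarizes the masks (any single nonzero
#' value maps to 1; genuinely multi-label masks are rejected), and enforces
#' shape agreement.
#'
#' @param row One manifest row (one-row data frame or named list).
#' @return A `volume_case` object.
#' @export
load_case <- function(row) {
  row <- as.list(row)
  vol <- read_nifti_array(row$volume[[1]])
  if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
  tum <- binarize_mask(read_nifti_array(row$tumor_mask[[1]]), row$tumor_mask[[1]])
  panc <- binarize_mask(read_nifti_array(row$pancreas_mask[[1]]), row$pancreas_mask[[1]])
  for (m in list(tum, panc)) {
    if (!identical(dim(m), dim(vol))) {
      stop_geometry(paste0("mask shape ", paste(dim(m), collapse = "x"),
                           " does not match volume shape ",
                           paste(dim(vol), collapse = "x"),
                           " for case ", row$case_id[[1]]))
    }
  }
  structure(
    list(
      case_id = as.character(row$case_id[[1]]),
      label = as.character(row$label[[1]]),
      intensities = vol, tumor_mask = tum, pancreas_mask = panc,
      spacing = c(1, 1, 1)
    ),
    class = "volume_case"
  )
}

#' Write a feature table to CSV
#'
#' Values are serialized with 17 significant digits so the write/read
#' round-trip reproduces every double bit-for-bit.
#'
#' @param table Tibble with `case_id` plus the 254 registry feature columns.
#' @param path Output CSV path.
#' @param region Region tag stored in the file's sibling metadata column
#'   order; informational.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, region = attr(table, "region")) {
  validate_feature_table(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_feature_table()].
#' @return A validated feature tibble (`case_id` + 254 registry columns).
#' @export
read_feature_table <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so the %.17g
  # serialization round-trips every double bit-for-bit
  df <- utils::read.csv(path, colClasses = c(case_id = "character"),
                        check.names = FALSE)
  tb <- as_tibble(df)
  validate_feature_table(tb)
  tb
}

validate_feature_table <- function(table) {
  want <- c("case_id", registry_names())
  missing <- setdiff(want, names(table))
  if (length(missing) > 0L) {
    stop_format(paste0("feature table missing column(s): ",
                       paste(head(missing, 5L), collapse = ", "),
                       if (length(missing) > 5L) ", ..."))
  }
  extra <- setdiff(names(table), want)
  if (length(extra) > 0L) {
    stop_format(paste0("feature table has unknown column(s): ",
                       paste(head(extra, 5L), collapse = ", ")))
  }
  if (!identical(names(table), want)) {
    stop_format("feature table columns are not in registry order")
  }
  vals <- as.matrix(table[, -1L])
  if (any(!is.finite(vals))) {
    stop_format("feature table contains non-finite values")
  }
  invisible(table)
}
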