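# Synthetic phantom cohorts.
#
# Each phantom is a small axial-slice CT-like volume: a constant background,
# a pancreas ellipsoid at a base intensity, a tumor ellipsoid at a distinct
# mean offset, and an additive stationary Gaussian random field (GRF) texture
# inside the pancreas. Class signal is planted as texture-heterogeneity
# differences (GRF amplitude and correlation length), not mean shifts, so the
# discriminative information lives in the texture features the pipeline
# extracts.

#' Phantom cohort configuration
#'
#' Bundles the geometry, intensity, and class-conditional texture parameters
#' that define a synthetic phantom cohort. Defaults emulate the study design:
#' 19 MSI-H cases against 76 controls (1:4), small axial volumes, and a
#' heterogeneity contrast between classes planted in both tumor and pancreas.
#'
#' @param n_cases,n_controls Number of MSI-H cases and controls.
#' @param volume_shape Integer vector `(rows, cols, slices)`.
#' @param pancreas_axes,tumor_axes Ellipsoid semi-axes in voxels; the tumor
#'   ellipsoid must be strictly contained in the pancreas ellipsoid.
#' @param base_intensity Pancreas mean intensity (arbitrary CT-like units).
#' @param tumor_offset Additive mean offset of the tumor relative to the
#'   pancreas (negative: hypodense tumor).
#' @param background Intensity outside the pancreas.
#' @param texture_sigma_case,texture_sigma_control GRF amplitudes (standard
#'   deviation of the additive texture) for the two classes.
#' @param corr_length_case,corr_length_control GRF correlation lengths in
#'   voxels (Gaussian smoothing width of the white-noise substrate).
#' @param effect_regions Character subset of `c("tumor", "pancreas")` naming
#'   the regions in which the case-class texture parameters apply; an empty
#'   vector yields a null cohort in which the label carries no signal.
#' @param seed Master seed; all per-case seeds derive from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_cases = 19L,
                           n_controls = 76L,
                           volume_shape = c(64L, 64L, 12L),
                           pancreas_axes = c(24, 18, 5),
                           tumor_axes = c(10, 8, 3),
                           base_intensity = 100,
                           tumor_offset = -20,
                           background = 40,
                           texture_sigma_case = 30,
                           texture_sigma_control = 10,
                           corr_length_case = 2,
                           corr_length_control = 4,
                           effect_regions = c("tumor", "pancreas"),
                           seed = 1L) {
  if (n_cases < 1L || n_controls < 1L) {
    stop_parameter("both classes must be nonempty (n_cases, n_controls >= 1)")
  }
  if (length(volume_shape) != 3L || any(volume_shape < 1L)) {
    stop_parameter("volume_shape must be three positive integers")
  }
  if (!all(tumor_axes < pancreas_axes)) {
    stop_geometry("tumor ellipsoid must be strictly contained in the pancreas ellipsoid")
  }
  if (any(pancreas_axes * 2 >= volume_shape)) {
    stop_geometry("pancreas ellipsoid does not fit inside the volume")
  }
  if (texture_sigma_case < 0 || texture_sigma_control < 0) {
    stop_parameter("texture sigmas must be nonnegative")
  }
  if (corr_length_case <= 0 || corr_length_control <= 0) {
    stop_parameter("correlation lengths must be positive")
  }
  if (max(corr_length_case, corr_length_control) >= min(volume_shape) / 2) {
    stop_parameter("correlation lengths must be < min(volume_shape)/2")
  }
  if (!all(effect_regions %in% c("tumor", "pancreas"))) {
    stop_parameter("effect_regions must be a subset of {tumor, pancreas}")
  }
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      volume_shape = as.integer(volume_shape),
      pancreas_axes = pancreas_axes, tumor_axes = tumor_axes,
      base_intensity = base_intensity, tumor_offset = tumor_offset,
      background = background,
      texture_sigma_case = texture_sigma_case,
      texture_sigma_control = texture_sigma_control,
      corr_length_case = corr_length_case,
      corr_length_control = corr_length_control,
      effect_regions = effect_regions,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

#' Stationary Gaussian random field
#'
#' White noise convolved with a separable Gaussian kernel of width
#' `corr_length`, then centered and rescaled so the empirical standard
#' deviation equals `sigma` exactly. Deterministic given `seed`.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param corr_length Positive correlation length in pixels.
#' @param sigma Nonnegative field amplitude.
#' @param seed Integer seed.
#' @return A `shape[1] x shape[2]` numeric matrix with mean 0 and sd `sigma`
#'   (all zeros when `sigma = 0`).
#' @examples
#' f <- gaussian_random_field(c(64, 64), corr_length = 3, sigma = 10, seed = 7)
#' c(mean(f), sd(f))
#' @export
gaussian_random_field <- function(shape, corr_length, sigma, seed) {
  if (corr_length <= 0) stop_parameter("corr_length must be positive")
  if (sigma < 0) stop_parameter("sigma must be nonnegative")
  shape <- as.integer(shape[1:2])
  if (sigma == 0) return(matrix(0, shape[1], shape[2]))
  noise <- withr::with_seed(seed, matrix(rnorm(prod(shape)), shape[1], shape[2]))
  field <- gaussian_smooth(noise, corr_length)
  field <- field - mean(field)
  s <- sd(field)
  if (s == 0) return(matrix(0, shape[1], shape[2]))
  field * (sigma / s)
}

# Separable Gaussian smoothing with edge renormalization (kernel mass inside
# the window sums to 1 at every position).
gaussian_smooth <- function(mat, width) {
  h <- max(1L, ceiling(3 * width))
  k <- exp(-(seq(-h, h))^2 / (2 * width^2))
  smooth_1d <- function(m, kernel) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (i in seq_along(kernel)) {
      off <- i - h - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kernel[i] * m[src[ok], ]
      wsum[ok] <- wsum[ok] + kernel[i]
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(mat, k)), k))
}

ellipsoid_mask <- function(shape, semi_axes) {
  ctr <- (shape + 1) / 2
  r <- (seq_len(shape[1]) - ctr[1]) / semi_axes[1]
  c_ <- (seq_len(shape[2]) - ctr[2]) / semi_axes[2]
  z <- (seq_len(shape[3]) - ctr[3]) / semi_axes[3]
  d2 <- outer(outer(r^2, c_^2, `+`), z^2, `+`)
  array(d2 <= 1, dim = shape)
}

# Texture parameters a region receives for a given label.
region_texture_params <- function(config, label, region) {
  is_case <- identical(label, "MSI-H")
  if (is_case && region %in% config$effect_regions) {
    list(sigma = config$texture_sigma_case, corr = config$corr_length_case)
  } else {
    list(sigma = config$texture_sigma_control, corr = config$corr_length_control)
  }
}

#' Generate one phantom case
#'
#' Builds a single synthetic volume with tumor and pancreas masks. The
#' pancreas ellipsoid sits at `base_intensity` over a constant background,
#' the tumor ellipsoid (strictly inside it) at `base_intensity +
#' tumor_offset`, and each region receives an additive per-slice GRF texture
#' whose amplitude and correlation length depend on the class label and
#' `effect_regions`.
#'
#' @param config A [phantom_config()].
#' @param label `"MSI-H"` or `"control"`.
#' @param case_seed Integer seed for this case's texture fields.
#' @param case_id Identifier stored on the returned object.
#' @return A `volume_case` object: list with `case_id`, `label`,
#'   `intensities`, `tumor_mask`, `pancreas_mask`, `spacing`.
#' @export
make_phantom_case <- function(config, label = c("control", "MSI-H"),
                              case_seed = config$seed, case_id = "case_001") {
  label <- match.arg(label)
  shape <- config$volume_shape
  panc <- ellipsoid_mask(shape, config$pancreas_axes)
  tum <- ellipsoid_mask(shape, config$tumor_axes)
  if (!all(panc[tum])) {
    stop_geometry("tumor ellipsoid is not contained in the pancreas ellipsoid")
  }
  vol <- array(config$background, dim = shape)
  vol[panc] <- config$base_intensity
  vol[tum] <- config$base_intensity + config$tumor_offset
  regions <- list(tumor = tum, pancreas = panc & !tum)
  for (ri in seq_along(regions)) {
    rname <- names(regions)[ri]
    rmask <- regions[[ri]]
    par <- region_texture_params(config, label, rname)
    for (z in seq_len(shape[3])) {
      mz <- rmask[, , z]
      if (!any(mz)) next
      grf <- gaussian_random_field(
        shape[1:2], par$corr, par$sigma,
        seed = derive_seed(case_seed, ri, z)
      )
      slice <- vol[, , z]
      slice[mz] <- slice[mz] + grf[mz]
      vol[, , z] <- slice
    }
  }
  structure(
    list(
      case_id = case_id, label = label, intensities = vol,
      tumor_mask = array(as.integer(tum), dim = shape),
      pancreas_mask = array(as.integer(panc), dim = shape),
      spacing = c(2.5, 2.5, 2.5)
    ),
    class = "volume_case"
  )
}

#' @export
print.volume_case <- function(x, ...) {
  cat(
    "<volume_case> ", x$case_id, " [", x$label, "] ",
    paste(dim(x$intensities), collapse = "x"),
    ", tumor ", sum(x$tumor_mask), " vox, pancreas ",
    sum(x$pancreas_mask), " vox\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a phantom cohort on disk
#'
#' Writes one NIfTI volume and two NIfTI masks per case plus a CSV manifest
#' (`case_id,label,volume,tumor_mask,pancreas_mask`). Fully reproducible from
#' `(config, config$seed)`; per-case seeds are derived from the master seed by
#' case index.
#'
#' @param config A [phantom_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest as a tibble (invisibly carries the per-case texture
#'   parameters in the `generation_log` attribute). A `manifest.csv` and a
#'   `generation_log.csv` are written alongside the volumes.
#' @export
generate_cohort <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", dir),
                   class = "msirad_io_error")
  }
  labels <- c(rep("MSI-H", config$n_cases), rep("control", config$n_controls))
  n <- length(labels)
  ids <- sprintf("case_%03d", seq_len(n))
  rows <- vector("list", n)
  log <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- derive_seed(config$seed, i)
    vc <- make_phantom_case(config, labels[i], case_seed = cs, case_id = ids[i])
    paths <- file.path(dir, paste0(ids[i], c("_vol.nii.gz", "_tumor.nii.gz", "_panc.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(vc$intensities, pixdim = vc$spacing), paths[1])
    RNifti::writeNifti(RNifti::asNifti(vc$tumor_mask, pixdim = vc$spacing), paths[2])
    RNifti::writeNifti(RNifti::asNifti(vc$pancreas_mask, pixdim = vc$spacing), paths[3])
    rows[[i]] <- tibble(
      case_id = ids[i], label = labels[i],
      volume = paths[1], tumor_mask = paths[2], pancreas_mask = paths[3]
    )
    tp_t <- region_texture_params(config, labels[i], "tumor")
    tp_p <- region_texture_params(config, labels[i], "pancreas")
    log[[i]] <- tibble(
      case_id = ids[i], label = labels[i], case_seed = cs,
      tumor_sigma = tp_t$sigma, tumor_corr = tp_t$corr,
      pancreas_sigma = tp_p$sigma, pancreas_corr = tp_p$corr
    )
  }
  manifest <- bind_rows(rows)
  glog <- bind_rows(log)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(glog, file.path(dir, "generation_log.csv"))
  attr(manifest, "generation_log") <- glog
  manifest
}

#' Generate a phantom cohort in memory
#'
#' Like [generate_cohort()] but returns the `volume_case` objects directly
#' instead of writing NIfTI files; convenient for pipelines that extract
#' features immediately.
#'
#' @inheritParams generate_cohort
#' @return A list with `cases` (list of `volume_case`) and `labels`.
#' @export
generate_cohort_cases <- function(config) {
  labels <- c(rep("MSI-H", config$n_cases), rep("control", config$n_controls))
  ids <- sprintf("case_%03d", seq_along(labels))
  cases <- lapply(seq_along(labels), function(i) {
    make_phantom_case(config, labels[i],
                      case_seed = derive_seed(config$seed, i), case_id = ids[i])
  })
  list(cases = cases, labels = labels)
}
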