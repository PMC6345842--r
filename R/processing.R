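#' Image processing configuration
#'
#' Collects the processing parameters applied between perturbation and
#' feature computation: interpolation to isotropic voxel spacings with
#' Gaussian anti-aliasing, intensity rounding, mask partial-volume
#' thresholding, re-segmentation and discretisation.
#'
#' @param spacings Target isotropic voxel spacings in mm.
#' @param beta Anti-alias smoothing parameter: the fraction of the signal
#'   band preserved at the target Nyquist frequency. Per axis, smoothing
#'   with sigma `beta * (s_target / s_source) / pi` source voxels is applied
#'   only where the grid is downsampled.
#' @param pv_threshold Partial-volume threshold for mask binarisation after
#'   interpolation; occupancy `>=` threshold becomes foreground.
#' @param resegment_range HU window `[lo, hi]` retained in the intensity
#'   mask (soft tissue for CT, e.g. `c(-300, 200)` for lung, `c(-150, 180)`
#'   for head-and-neck).
#' @param outlier_sigma Multiplier of the sigma-outlier rule: voxels further
#'   than `outlier_sigma` standard deviations from the ROI mean are removed
#'   from the intensity mask.
#' @param bin_numbers Fixed-bin-number discretisation settings.
#' @param bin_sizes Fixed-bin-size discretisation settings in HU.
#' @return An object of class `processing_config`.
#' @export
processing_config <- function(spacings = c(1, 2, 3, 4), beta = 0.93,
                              pv_threshold = 0.5,
                              resegment_range = c(-300, 200),
                              outlier_sigma = 3,
                              bin_numbers = c(8, 16, 32, 64),
                              bin_sizes = c(6, 12, 18, 24)) {
  if (any(spacings <= 0)) stop("spacings must be positive")
  if (length(resegment_range) != 2 ||
      resegment_range[1] >= resegment_range[2]) {
    stop("resegment_range must be [lo, hi] with lo < hi")
  }
  if (pv_threshold <= 0 || pv_threshold >= 1) {
    stop("partial-volume threshold must lie in (0, 1)")
  }
  if (any(bin_numbers < 2)) stop("bin numbers must be >= 2")
  if (any(bin_sizes <= 0)) stop("bin sizes must be > 0")
  structure(list(spacings = as.numeric(spacings), beta = beta,
                 pv_threshold = pv_threshold,
                 resegment_range = as.numeric(resegment_range),
                 outlier_sigma = outlier_sigma,
                 bin_numbers = as.numeric(bin_numbers),
                 bin_sizes = as.numeric(bin_sizes)),
            class = "processing_config")
}

#' Interpolate image and mask to an isotropic grid
#'
#' Resamples the image trilinearly to the target isotropic spacing with
#' prior per-axis Gaussian anti-alias smoothing (only along axes that are
#' downsampled; smoothing sigma is `beta * ratio / pi` source voxels for a
#' spacing ratio `ratio > 1`). Intensities are rounded to the nearest
#' integer HU (half away from zero); the fractional mask is resampled
#' trilinearly without smoothing and binarised at the partial-volume
#' threshold. The output grid shares its physical centre with the input
#' grid.
#'
#' @param image A [vol_image()].
#' @param mask A [roi_mask()] or [frac_mask()].
#' @param spacing Target isotropic spacing in mm.
#' @param config A [processing_config()].
#' @return List with resampled `image` ([vol_image()]) and binary `mask`
#'   ([roi_mask()], kind `"original"`).
#' @export
interpolate_to_isotropic <- function(image, mask, spacing,
                                     config = processing_config()) {
  stopifnot(spacing > 0)
  fm <- as_frac_mask(mask)
  d_in <- dim(image$voxels)
  s_in <- image$spacing

  # output grid: same physical centre, extent covered at the new spacing
  n_out <- pmax(1L, as.integer(ceiling(d_in * s_in / spacing - 1e-9)))
  centre <- image$origin + (d_in - 1) * s_in / 2
  o_out <- centre - (n_out - 1) * spacing / 2

  ratio <- spacing / s_in
  sigma_vox <- ifelse(ratio > 1 + 1e-9, config$beta * ratio / pi, 0)
  smoothed <- if (any(sigma_vox > 0)) {
    gaussian_blur(image$voxels, sigma_vox)
  } else {
    image$voxels
  }

  pts <- grid_centres(n_out, rep(spacing, 3), o_out)
  idx <- phys_to_index(pts, s_in, image$origin)
  img_v <- round_half_away(
    array(trilinear_sample(smoothed, idx, outside = "clamp"), dim = n_out))
  msk_v <- array(trilinear_sample(fm$values, idx, outside = 0), dim = n_out)

  out_mask <- roi_mask(msk_v >= config$pv_threshold, rep(spacing, 3), o_out,
                       kind = "original")
  if (mask_volume(out_mask) == 0) {
    stop("interpolated mask is empty at spacing ", spacing, " mm",
         call. = FALSE)
  }
  list(image = vol_image(img_v, rep(spacing, 3), o_out), mask = out_mask)
}

#' Re-segment the intensity mask
#'
#' Derives the intensity mask from the morphological mask by keeping only
#' voxels inside the configured HU window, then removing voxels deviating
#' more than `outlier_sigma` standard deviations from the mean of the
#' range-filtered ROI (one pass, no iteration). The morphological mask is
#' untouched.
#'
#' @param image A [vol_image()].
#' @param mask The morphological [roi_mask()].
#' @param config A [processing_config()].
#' @return The intensity [roi_mask()] (kind `"intensity"`).
#' @export
resegment <- function(image, mask, config = processing_config()) {
  check_same_grid(image, mask)
  if (mask_volume(mask) == 0) stop("morphological mask is empty",
                                   call. = FALSE)
  v <- image$voxels
  lo <- config$resegment_range[1]
  hi <- config$resegment_range[2]
  keep <- mask$labels & v >= lo & v <= hi
  if (!any(keep)) stop("re-segmentation emptied the intensity mask",
                       call. = FALSE)
  vals <- v[keep]
  mu <- mean(vals)
  sg <- stats::sd(vals)
  if (is.finite(sg) && sg > 0) {
    keep <- keep & abs(v - mu) <= config$outlier_sigma * sg
  }
  if (!any(keep)) stop("re-segmentation emptied the intensity mask",
                       call. = FALSE)
  roi_mask(keep, mask$spacing, mask$origin, kind = "intensity")
}

#' Discretise ROI intensities into grey levels
#'
#' Maps HU values inside the intensity mask to integer grey levels `>= 1`.
#' With `method = "fixed_bin_number"`,
#' `g = min(N, floor(N (x - min) / (max - min)) + 1)`; a constant ROI maps
#' every voxel to level 1. With `method = "fixed_bin_size"`,
#' `g = floor((x - lo) / w) + 1`, anchored at the lower edge `lo` of the
#' re-segmentation range so that grey levels are comparable across images.
#'
#' @param x Numeric vector of HU values inside the intensity mask.
#' @param method `"fixed_bin_number"` or `"fixed_bin_size"`.
#' @param value Number of bins `N`, or bin width `w` in HU.
#' @param config A [processing_config()] (supplies the fixed-bin-size
#'   anchor).
#' @return Integer vector of grey levels, with attribute `n_levels` (the
#'   nominal number of levels of the discretisation).
#' @export
discretise <- function(x, method = c("fixed_bin_number", "fixed_bin_size"),
                       value, config = processing_config()) {
  method <- match.arg(method)
  if (length(x) == 0) stop("empty intensity set", call. = FALSE)
  if (method == "fixed_bin_number") {
    nb <- as.integer(value)
    rng <- max(x) - min(x)
    if (rng == 0) {
      g <- rep(1L, length(x))
    } else {
      g <- pmin(nb, floor(nb * (x - min(x)) / rng) + 1)
    }
    attr(g, "n_levels") <- nb
  } else {
    w <- as.numeric(value)
    lo <- config$resegment_range[1]
    g <- floor((x - lo) / w) + 1
    g <- pmax(g, 1)
    attr(g, "n_levels") <- max(ceiling((config$resegment_range[2] - lo) / w),
                               max(g))
  }
  storage.mode(g) <- "integer"
  g
}
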