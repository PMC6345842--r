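#' Fractional occupancy mask
#'
#' Rotation and translation resample the ROI mask trilinearly, which turns
#' binary labels into fractional occupancies in \[0, 1\]. The fraction is
#' carried through the processing chain and only binarised at the
#' partial-volume thresholding step of [interpolate_to_isotropic()].
#'
#' @param values 3D numeric array with values in \[0, 1\].
#' @param spacing,origin Grid geometry in mm.
#' @return An object of class `frac_mask`.
#' @export
frac_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
    stop("fractional occupancies must lie in [0, 1]")
  }
  structure(list(values = pmin(pmax(values, 0), 1),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "frac_mask")
}

#' @rdname frac_mask
#' @param mask A [roi_mask()] or `frac_mask`.
#' @export
as_frac_mask <- function(mask) {
  if (inherits(mask, "frac_mask")) return(mask)
  frac_mask(array(as.numeric(mask$labels), dim = dim(mask$labels)),
            spacing = mask$spacing, origin = mask$origin)
}

# fractional occupancy values of either mask flavour
mask_values <- function(mask) {
  if (inherits(mask, "frac_mask")) mask$values
  else array(as.numeric(mask$labels), dim = dim(mask$labels))
}

#' Binarise a fractional mask
#'
#' @param mask A [frac_mask()] (a binary [roi_mask()] passes through).
#' @param threshold Partial-volume threshold; occupancy `>= threshold`
#'   becomes foreground.
#' @param kind Mask kind for the result.
#' @return A [roi_mask()].
#' @export
binarise_mask <- function(mask, threshold = 0.5, kind = "original") {
  v <- mask_values(mask)
  roi_mask(v >= threshold, spacing = mask$spacing, origin = mask$origin,
           kind = kind)
}

# centre of mass of a mask in physical mm
mask_com <- function(mask) {
  v <- mask_values(mask)
  d <- dim(v)
  w <- sum(v)
  if (w == 0) stop("mask is empty", call. = FALSE)
  pts <- grid_centres(d, mask$spacing, mask$origin)
  colSums(pts * as.vector(v)) / w
}

#' Rotate image and mask in the axial plane
#'
#' Applies an affine in-plane (x, y) rotation about the z-axis by `theta`
#' degrees, centred by default on the ROI centre of mass so the ROI stays in
#' the grid. The image is resampled trilinearly with edge replication; the
#' mask is resampled to fractional occupancy (zero fill outside the grid).
#' The grid geometry is unchanged. `theta = 0` is an exact no-op.
#'
#' @param image A [vol_image()].
#' @param mask A [roi_mask()] or [frac_mask()].
#' @param theta Rotation angle in degrees (counter-clockwise in the xy
#'   plane).
#' @param centre `"roi"` (ROI centre of mass, default) or `"image"` (grid
#'   centre), or a length-2 numeric (x, y) in mm.
#' @return List with perturbed `image` and fractional `mask`.
#' @export
rotate_axial <- function(image, mask, theta, centre = "roi") {
  stopifnot(is.finite(theta))
  fm <- as_frac_mask(mask)
  if (theta == 0) {
    return(list(image = image, mask = fm))
  }
  d <- dim(image$voxels)
  ctr <- resolve_centre(centre, image, fm)
  th <- theta * pi / 180
  # output value at p comes from the inverse-rotated location
  cs <- cos(-th)
  sn <- sin(-th)
  pts <- grid_centres(d, image$spacing, image$origin)
  dx <- pts[, 1] - ctr[1]
  dy <- pts[, 2] - ctr[2]
  src <- cbind(ctr[1] + cs * dx - sn * dy,
               ctr[2] + sn * dx + cs * dy,
               pts[, 3])
  idx <- phys_to_index(src, image$spacing, image$origin)
  new_img <- array(trilinear_sample(image$voxels, idx, outside = "clamp"),
                   dim = d)
  new_msk <- array(trilinear_sample(fm$values, idx, outside = 0), dim = d)
  if (max(new_msk) < 0.5) {
    stop("rotation moved the ROI outside the grid", call. = FALSE)
  }
  list(image = vol_image(new_img, image$spacing, image$origin),
       mask = frac_mask(new_msk, image$spacing, image$origin))
}

resolve_centre <- function(centre, image, fm) {
  if (is.numeric(centre)) return(centre[1:2])
  if (identical(centre, "image")) {
    d <- dim(image$voxels)
    return(image$origin[1:2] + (d[1:2] - 1) * image$spacing[1:2] / 2)
  }
  mask_com(fm)[1:2]
}

#' Estimate the additive noise level of an image
#'
#' Structure-robust noise estimate used to scale the noise perturbation:
#' the discrete 1D Laplacian `x[i-1] - 2 x[i] + x[i+1]` is computed along
#' each axis (it annihilates constant and linear trends), normalised by
#' `sqrt(6)` so that for pure i.i.d. noise its standard deviation equals the
#' noise sigma, and the sigma is estimated from the pooled residuals by the
#' median absolute deviation. An optional body mask restricts the estimate
#' to tissue (default: voxels above -500 HU, excluding air in CT).
#'
#' @param image A [vol_image()].
#' @param body_threshold Minimum HU for a voxel to enter the estimate; `NULL`
#'   uses all voxels.
#' @return Estimated noise standard deviation in HU (>= 0). A constant image
#'   returns 0 with a warning.
#' @export
estimate_noise_sd <- function(image, body_threshold = -500) {
  vox <- image$voxels
  if (length(vox) < 1000) {
    stop("image too small for noise estimation (< 1000 voxels)",
         call. = FALSE)
  }
  if (max(vox) == min(vox)) {
    warning("constant image: noise SD estimated as 0")
    return(0)
  }
  d <- dim(vox)
  res <- c()
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 3) next
    mid <- index_axis(vox, 2:(n - 1), ax)
    lo <- index_axis(vox, 1:(n - 2), ax)
    hi <- index_axis(vox, 3:n, ax)
    r <- (lo - 2 * mid + hi) / sqrt(6)
    if (!is.null(body_threshold)) {
      keep <- mid > body_threshold
      r <- r[keep]
    }
    res <- c(res, as.vector(r))
  }
  if (length(res) == 0) return(0)
  max(stats::mad(res, center = 0), 0)
}

#' Add Gaussian noise to an image
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation `sigma` to
#' every voxel. Deterministic given `seed`; the mask is untouched by
#' construction.
#'
#' @param image A [vol_image()].
#' @param sigma Noise standard deviation in HU (>= 0).
#' @param seed Integer seed.
#' @return Perturbed [vol_image()].
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  if (!is.finite(sigma) || sigma < 0) {
    stop("noise sigma must be >= 0", call. = FALSE)
  }
  if (sigma == 0) return(image)
  d <- dim(image$voxels)
  noise <- with_seed(seed, rnorm(prod(d), mean = 0, sd = sigma))
  vol_image(image$voxels + array(noise, dim = d), image$spacing, image$origin)
}

#' Translate image and mask by sub-voxel fractions
#'
#' Shifts image and mask by `eta * spacing` mm along each axis (a fraction
#' of the voxel spacing per axis), realised by trilinear resampling. The
#' mask becomes fractional. `eta = c(0, 0, 0)` is an exact no-op.
#'
#' @param image A [vol_image()].
#' @param mask A [roi_mask()] or [frac_mask()].
#' @param eta Length-3 numeric, per-axis shift as a fraction of voxel
#'   spacing, each in \[0, 1).
#' @return List with perturbed `image` and fractional `mask`.
#' @export
translate <- function(image, mask, eta) {
  eta <- rep(as.numeric(eta), length.out = 3)
  if (any(eta < 0 | eta >= 1)) {
    stop("translation fractions must lie in [0, 1)", call. = FALSE)
  }
  fm <- as_frac_mask(mask)
  if (all(eta == 0)) return(list(image = image, mask = fm))
  d <- dim(image$voxels)
  shift_mm <- eta * image$spacing
  pts <- grid_centres(d, image$spacing, image$origin)
  src <- cbind(pts[, 1] - shift_mm[1], pts[, 2] - shift_mm[2],
               pts[, 3] - shift_mm[3])
  idx <- phys_to_index(src, image$spacing, image$origin)
  new_img <- array(trilinear_sample(image$voxels, idx, outside = "clamp"),
                   dim = d)
  new_msk <- array(trilinear_sample(fm$values, idx, outside = 0), dim = d)
  list(image = vol_image(new_img, image$spacing, image$origin),
       mask = frac_mask(new_msk, image$spacing, image$origin))
}

#' Permute translation fractions over the axes
#'
#' Expands `m` translation fractions into the full set of `m^e` per-axis
#' tuples (default `e = 3` spatial axes); each tuple yields one perturbed
#' image in a chain.
#'
#' @param fractions Numeric vector of voxel-spacing fractions.
#' @param axes Number of axes to permute over.
#' @return A matrix with one row per tuple and `axes` columns.
#' @export
permute_translations <- function(fractions, axes = 3) {
  if (length(fractions) == 0) {
    stop("translation fraction list is empty", call. = FALSE)
  }
  grid <- do.call(expand.grid, rep(list(fractions), axes))
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, paste0("eta_", c("x", "y", "z")[seq_len(axes)]))
  m
}

#' Grow or shrink a mask by a volume fraction
#'
#' Adapts the ROI volume by the signed fraction `tau`: the Euclidean signed
#' distance to the mask boundary is computed (negative inside), voxels are
#' ranked by that distance and the `round((1 + tau) * N0)` closest voxels
#' form the new mask. Growth (`tau > 0`) therefore yields a superset and
#' shrinkage (`tau < 0`) a subset of the input, with the voxel count hitting
#' the target exactly up to distance ties (broken deterministically by array
#' order).
#'
#' @param mask A [roi_mask()].
#' @param tau Signed volume-change fraction, `|tau| < 1`.
#' @return Adapted [roi_mask()].
#' @export
adapt_volume <- function(mask, tau) {
  if (!is.finite(tau) || abs(tau) >= 1) {
    stop("volume fraction tau must satisfy |tau| < 1", call. = FALSE)
  }
  n0 <- mask_volume(mask)
  if (n0 == 0) stop("mask is empty", call. = FALSE)
  if (tau == 0) return(mask)
  target <- as.integer(round((1 + tau) * n0))
  if (target < 1) {
    stop("volume shrinkage would eliminate the mask", call. = FALSE)
  }
  sdist <- signed_distance(mask)
  ord <- order(sdist, seq_along(sdist))
  keep <- ord[seq_len(min(target, length(ord)))]
  labels <- array(FALSE, dim = dim(mask$labels))
  labels[keep] <- TRUE
  roi_mask(labels, mask$spacing, mask$origin, kind = mask$kind)
}

# Signed Euclidean distance: negative inside the mask, positive outside,
# measured voxel-centre to voxel-centre with physical spacing.
signed_distance <- function(mask) {
  d <- dim(mask$labels)
  fg <- as.vector(mask$labels)
  din <- sqrt(cpp_edt_sq(!fg, as.integer(d), mask$spacing))  # to background
  dout <- sqrt(cpp_edt_sq(fg, as.integer(d), mask$spacing))  # to foreground
  ifelse(fg, -din, dout)
}

#' Compute 3D SLIC supervoxels
#'
#' Simple linear iterative clustering over a volumetric image: cluster
#' centres start on a regular grid with physical interval `S` (derived from
#' the target supervoxel volume), and voxels are assigned to the nearest
#' centre in a combined intensity/space metric
#' `D^2 = dI^2 + compactness^2 (ds/S)^2`. Fully deterministic.
#'
#' @param image A [vol_image()].
#' @param target_volume_mm3 Desired average supervoxel volume in mm^3.
#' @param compactness Weight of spatial vs intensity distance (HU units).
#' @param iterations Number of assign/update sweeps.
#' @return Integer 3D array of supervoxel labels (a partition: every voxel
#'   carries exactly one label >= 1).
#' @export
slic_supervoxels <- function(image, target_volume_mm3 = 150,
                             compactness = 20, iterations = 10) {
  S <- target_volume_mm3^(1 / 3)
  lab <- cpp_slic(as.vector(image$voxels), as.integer(dim(image$voxels)),
                  image$spacing, S, compactness, as.integer(iterations))
  array(lab, dim = dim(image$voxels))
}

#' Randomise an ROI contour with supervoxels
#'
#' Perturbs the mask rim by randomly selecting supervoxels based on their
#' fractional overlap `f` with the original mask: supervoxels with
#' `f >= keep_threshold` are always kept, those with `0 < f < keep_threshold`
#' are kept independently with probability `f`, and non-overlapping
#' supervoxels are never added. The ROI core is thus preserved while the
#' boundary is resampled. Deterministic given `seed`.
#'
#' @param image A [vol_image()] used for intensity-based clustering.
#' @param mask A [roi_mask()].
#' @param seed Integer seed for the random selection.
#' @param target_volume_mm3,compactness,iterations SLIC settings, see
#'   [slic_supervoxels()].
#' @param keep_threshold Overlap fraction above which a supervoxel is always
#'   kept.
#' @param supervoxels Optional precomputed label array from
#'   [slic_supervoxels()] (the expensive part), for reuse across
#'   repetitions.
#' @return Randomised [roi_mask()].
#' @export
contour_randomise <- function(image, mask, seed = 1L,
                              target_volume_mm3 = 150, compactness = 20,
                              iterations = 10, keep_threshold = 0.9,
                              supervoxels = NULL) {
  check_same_grid(image, mask)
  n0 <- mask_volume(mask)
  if (n0 == 0) stop("mask is empty", call. = FALSE)
  vol_roi <- n0 * prod(mask$spacing)
  if (target_volume_mm3 > vol_roi) {
    stop("supervoxel volume exceeds the ROI volume; reduce target_volume_mm3",
         call. = FALSE)
  }
  if (is.null(supervoxels)) {
    supervoxels <- slic_supervoxels(image, target_volume_mm3, compactness,
                                    iterations)
  }
  sv <- as.vector(supervoxels)
  fg <- as.vector(mask$labels)
  size_all <- tabulate(sv)
  size_fg <- tabulate(sv[fg], nbins = length(size_all))
  f <- ifelse(size_all > 0, size_fg / size_all, 0)
  keep <- with_seed(seed, {
    u <- stats::runif(length(f))
    f >= keep_threshold | (f > 0 & u < f)
  })
  labels <- array(keep[sv], dim = dim(mask$labels))
  if (!any(labels)) {
    # extreme draw removed everything: fall back to always-kept core
    labels <- array(f[sv] >= keep_threshold, dim = dim(mask$labels))
  }
  if (!any(labels)) stop("contour randomisation emptied the mask",
                         call. = FALSE)
  roi_mask(labels, mask$spacing, mask$origin, kind = mask$kind)
}
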