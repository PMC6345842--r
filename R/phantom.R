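#' Synthetic phantom specification
#'
#' Describes a deterministic digital phantom: an ellipsoidal ROI embedded in
#' a uniform background, with a choice of foreground intensity model and
#' optional additive Gaussian noise. The phantom stands in for a patient CT
#' in tests and examples; the same seed always reproduces the same voxels.
#'
#' @param shape Integer length-3 grid dimensions (x, y, z).
#' @param spacing Voxel size in mm, length 3 (or 1, recycled).
#' @param centre Ellipsoid centre in mm; default grid centre.
#' @param radii Ellipsoid semi-axes in mm, length 3 (or 1 for a sphere).
#' @param background Background intensity in HU.
#' @param foreground Foreground model: `"constant"` (value `fg_value`),
#'   `"ramp"` (linear gradient along x spanning `fg_value` +/- `fg_range`/2),
#'   or `"texture"` (spatially smoothed random field quantised to
#'   `fg_levels` grey levels spanning `fg_value` +/- `fg_range`/2).
#' @param fg_value Mean foreground intensity (HU).
#' @param fg_range Intensity span of ramp/texture models (HU).
#' @param fg_levels Number of grey levels for the texture model.
#' @param noise_sd Standard deviation of additive Gaussian noise (HU);
#'   0 disables noise.
#' @param seed Integer random seed; with the rest of the spec it fully
#'   determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), spacing = c(1, 1, 1),
                         centre = NULL, radii = 10, background = -50,
                         foreground = c("constant", "ramp", "texture"),
                         fg_value = 40, fg_range = 60, fg_levels = 16,
                         noise_sd = 0, seed = 1L) {
  foreground <- match.arg(foreground)
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(radii) == 1) radii <- rep(radii, 3)
  spacing <- as.numeric(spacing)
  radii <- as.numeric(radii)
  if (length(shape) != 3 || any(shape < 1)) stop("bad grid shape")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(radii <= 0)) stop("radii must be positive")
  if (is.null(centre)) centre <- (shape - 1) * spacing / 2
  extent <- (shape - 1) * spacing
  if (any(centre - radii < 0) || any(centre + radii > extent)) {
    stop("ROI does not fit inside the grid", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape = shape, spacing = spacing, centre = as.numeric(centre),
                 radii = radii, background = background,
                 foreground = foreground, fg_value = fg_value,
                 fg_range = fg_range, fg_levels = as.integer(fg_levels),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom image and mask
#'
#' The mask is the set of voxels whose centres satisfy the ellipsoid
#' equation (voxel-centre rule); the image holds the foreground model inside
#' the ROI, the background value outside, plus optional i.i.d. Gaussian
#' noise over the whole grid. The output is a pure function of the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([vol_image()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  xs <- axis_coords(d[1], spec$spacing[1], 0)
  ys <- axis_coords(d[2], spec$spacing[2], 0)
  zs <- axis_coords(d[3], spec$spacing[3], 0)
  u2 <- ((xs - spec$centre[1]) / spec$radii[1])^2
  v2 <- ((ys - spec$centre[2]) / spec$radii[2])^2
  w2 <- ((zs - spec$centre[3]) / spec$radii[3])^2
  rr <- outer(outer(u2, v2, "+"), w2, "+")
  labels <- rr <= 1
  vox <- array(spec$background, dim = d)

  fg <- which(labels)
  if (spec$foreground == "constant") {
    vox[fg] <- spec$fg_value
  } else if (spec$foreground == "ramp") {
    xn <- (xs - (spec$centre[1] - spec$radii[1])) / (2 * spec$radii[1])
    ramp <- spec$fg_value + (xn - 0.5) * spec$fg_range
    vox[fg] <- ramp[((fg - 1) %% d[1]) + 1]
  } else { # texture
    field <- with_seed(derive_seed(spec$seed, "texture"), {
      raw <- array(rnorm(prod(d)), dim = d)
      gaussian_blur(raw, sigma_vox = c(1.5, 1.5, 1.5))
    })
    qs <- quantile(field[fg], probs = seq(0, 1, length.out = spec$fg_levels + 1))
    lev <- cut(field[fg], breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    lev[is.na(lev)] <- 1L
    values <- spec$fg_value +
      (seq_len(spec$fg_levels) - (spec$fg_levels + 1) / 2) /
        max(spec$fg_levels - 1, 1) * spec$fg_range
    vox[fg] <- values[lev]
  }

  if (spec$noise_sd > 0) {
    noise <- with_seed(derive_seed(spec$seed, "noise"),
                       rnorm(prod(d), sd = spec$noise_sd))
    vox <- vox + array(noise, dim = d)
  }
  list(image = vol_image(vox, spacing = spec$spacing, origin = c(0, 0, 0)),
       mask = roi_mask(labels, spacing = spec$spacing, origin = c(0, 0, 0)))
}

#' Serialise / deserialise a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path File path; for `phantom_spec_to_yaml`, `NULL` returns the
#'   YAML text instead of writing.
#' @return `phantom_spec_to_yaml`: path or YAML string;
#'   `phantom_spec_from_yaml`: a [phantom_spec()].
#' @export
phantom_spec_to_yaml <- function(spec, path = NULL) {
  txt <- yaml::as.yaml(unclass(spec))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname phantom_spec_to_yaml
#' @export
phantom_spec_from_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(phantom_spec, lst)
}
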