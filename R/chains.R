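#' Perturbation chain definition
#'
#' A chain combines up to five perturbation operators; its label lists the
#' operators in the conventional order (subset of "RNTVC") while the actual
#' application order is always rotation -> noise -> translation ->
#' isotropic interpolation -> volume adaptation -> contour randomisation.
#' The parameter grids are fully permuted (Cartesian product), translation
#' contributing `m^3` per-axis tuples for `m` fractions, so the number of
#' perturbed images equals the product of the grid sizes.
#'
#' @param label Chain label, e.g. `"RVC"`.
#' @param angles Rotation angles theta in degrees (`NULL` if the chain has
#'   no rotation). Default range \[-13, 13\] degrees.
#' @param noise_reps Number of noise-addition repetitions (0 = no noise).
#' @param translations Translation fractions eta of the voxel spacing, each
#'   in \[0, 1); permuted over the three axes.
#' @param taus Volume adaptation fractions, each in \[-0.28, 0.28\] by
#'   default convention.
#' @param contour_reps Number of contour-randomisation repetitions (0 =
#'   none).
#' @param supervoxel Settings list for contour randomisation (see
#'   [contour_randomise()]).
#' @return An object of class `perturbation_chain`.
#' @export
perturbation_chain <- function(label, angles = NULL, noise_reps = 0,
                               translations = NULL, taus = NULL,
                               contour_reps = 0,
                               supervoxel = list(target_volume_mm3 = 150,
                                                 compactness = 20,
                                                 keep_threshold = 0.9)) {
  ops <- chain_ops(label)
  if (("R" %in% ops) != (length(angles) > 0)) {
    stop("chain label and rotation grid disagree", call. = FALSE)
  }
  if (("N" %in% ops) != (noise_reps > 0)) {
    stop("chain label and noise repetitions disagree", call. = FALSE)
  }
  if (("T" %in% ops) != (length(translations) > 0)) {
    stop("chain label and translation grid disagree", call. = FALSE)
  }
  if (("V" %in% ops) != (length(taus) > 0)) {
    stop("chain label and volume grid disagree", call. = FALSE)
  }
  if (("C" %in% ops) != (contour_reps > 0)) {
    stop("chain label and contour repetitions disagree", call. = FALSE)
  }
  structure(list(label = label, angles = angles,
                 noise_reps = as.integer(noise_reps),
                 translations = translations, taus = taus,
                 contour_reps = as.integer(contour_reps),
                 supervoxel = supervoxel),
            class = "perturbation_chain")
}

chain_ops <- function(label) {
  ops <- strsplit(label, "")[[1]]
  if (length(ops) == 0 || !all(ops %in% c("R", "N", "T", "V", "C")) ||
      anyDuplicated(ops)) {
    stop("invalid chain label: ", label, call. = FALSE)
  }
  ops
}

#' Number of perturbed images a chain generates
#'
#' @param chain A [perturbation_chain()].
#' @return Integer: the product of the parameter grid sizes (translation
#'   contributes `m^3`).
#' @export
chain_size <- function(chain) {
  n <- 1L
  if (length(chain$angles)) n <- n * length(chain$angles)
  if (chain$noise_reps > 0) n <- n * chain$noise_reps
  if (length(chain$translations)) n <- n * length(chain$translations)^3
  if (length(chain$taus)) n <- n * length(chain$taus)
  if (chain$contour_reps > 0) n <- n * chain$contour_reps
  as.integer(n)
}

#' Default registry of the 18 perturbation chains
#'
#' All 18 chain labels combining rotation (R), noise addition (N),
#' translation (T), volume adaptation (V) and contour randomisation (C)
#' used in the robustness study, with default parameter grids spanning the
#' conventional ranges (theta in \[-13, 13\] degrees, eta in \[0, 0.75\],
#' tau in \[-0.28, 0.28\]). Grids are configuration, not constants: any
#' registry entry can be replaced via [perturbation_chain()], e.g. to match
#' a published per-chain parameter table.
#'
#' @return Named list of [perturbation_chain()] objects.
#' @export
default_chain_registry <- function() {
  tau5 <- c(-0.28, -0.14, 0, 0.14, 0.28)
  reg <- list(
    perturbation_chain("R", angles = seq(-13, 13, by = 1)),
    perturbation_chain("N", noise_reps = 30),
    perturbation_chain("T", translations = c(0, 0.25, 0.5)),
    perturbation_chain("V", taus = seq(-0.28, 0.28, by = 0.02)),
    perturbation_chain("C", contour_reps = 30),
    perturbation_chain("RT", angles = c(-13, -6, 6, 13),
                       translations = c(0.25, 0.75)),
    perturbation_chain("RNT", angles = c(-13, -6, 6, 13), noise_reps = 1,
                       translations = c(0.25, 0.75)),
    perturbation_chain("RV", angles = c(-13, -8, -3, 3, 8, 13),
                       taus = tau5),
    perturbation_chain("RC", angles = c(-13, 0, 13), contour_reps = 9),
    perturbation_chain("TV", translations = c(0.25, 0.75), taus = tau5),
    perturbation_chain("TC", translations = c(0.25, 0.5, 0.75),
                       contour_reps = 1),
    perturbation_chain("RTC", angles = c(-13, -6, 6, 13),
                       translations = c(0.25, 0.75), contour_reps = 1),
    perturbation_chain("RNTC", angles = c(-13, -6, 6, 13), noise_reps = 1,
                       translations = c(0.25, 0.75), contour_reps = 1),
    perturbation_chain("VC", taus = tau5, contour_reps = 6),
    perturbation_chain("RVC", angles = c(-13, 13), taus = tau5,
                       contour_reps = 3),
    perturbation_chain("RNVC", angles = c(-13, 13), noise_reps = 1,
                       taus = tau5, contour_reps = 3),
    perturbation_chain("TVC", translations = c(0.25, 0.75), taus = tau5,
                       contour_reps = 1),
    perturbation_chain("NTVC", noise_reps = 1,
                       translations = c(0.25, 0.75), taus = tau5,
                       contour_reps = 1))
  stats::setNames(reg, vapply(reg, function(ch) ch$label, character(1)))
}

# Cartesian product of a chain's parameter grids, one row per perturbed
# sample; unused operators contribute NA columns.
chain_grid <- function(chain) {
  parts <- list(
    theta = if (length(chain$angles)) chain$angles else NA_real_,
    noise_rep = if (chain$noise_reps > 0) seq_len(chain$noise_reps)
                else NA_integer_)
  if (length(chain$translations)) {
    tr <- permute_translations(chain$translations)
    parts$trans_idx <- seq_len(nrow(tr))
  } else {
    tr <- NULL
    parts$trans_idx <- NA_integer_
  }
  parts$tau <- if (length(chain$taus)) chain$taus else NA_real_
  parts$contour_rep <- if (chain$contour_reps > 0)
    seq_len(chain$contour_reps) else NA_integer_
  g <- expand.grid(parts, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(tr)) {
    g$eta_x <- tr[g$trans_idx, 1]
    g$eta_y <- tr[g$trans_idx, 2]
    g$eta_z <- tr[g$trans_idx, 3]
  } else {
    g$eta_x <- NA_real_
    g$eta_y <- NA_real_
    g$eta_z <- NA_real_
  }
  g$trans_idx <- NULL
  g$sample_id <- seq_len(nrow(g))
  g
}

#' Expand a perturbation chain into perturbed samples
#'
#' Applies every parameter combination of the chain to the image and mask
#' in the fixed processing order (rotation, noise, translation on the
#' native grid; isotropic interpolation; volume adaptation; contour
#' randomisation on the interpolated grid). One sample is produced per
#' element of the Cartesian product of the grids. Each sample carries its
#' provenance (chain label, concrete parameter tuple, per-sample seed) and
#' is bit-reproducible from it.
#'
#' @param chain A [perturbation_chain()].
#' @param image A [vol_image()] on its native grid.
#' @param mask A [roi_mask()] on the same grid.
#' @param config A [processing_config()].
#' @param spacing Target isotropic spacing (mm) for the interpolation step.
#' @param base_seed Base seed; per-sample seeds are derived from it, the
#'   chain label and the parameter tuple.
#' @param noise_sd Noise standard deviation in HU; `NULL` estimates it once
#'   from the input image via [estimate_noise_sd()].
#' @return List of samples, each a list with `image` (processed
#'   [vol_image()]), `mask` (morphological [roi_mask()]) and `provenance`.
#' @export
expand_chain <- function(chain, image, mask, config = processing_config(),
                         spacing = config$spacings[1], base_seed = 1L,
                         noise_sd = NULL) {
  check_same_grid(image, mask)
  grid <- chain_grid(chain)
  needs_noise <- chain$noise_reps > 0
  if (needs_noise && is.null(noise_sd)) {
    noise_sd <- estimate_noise_sd(image)
  }
  sv_cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(grid)), function(r) {
    p <- grid[r, ]
    apply_chain_sample(chain, image, mask, p, config, spacing, base_seed,
                       noise_sd, sv_cache)
  })
}

apply_chain_sample <- function(chain, image, mask, p, config, spacing,
                               base_seed, noise_sd, sv_cache = NULL) {
  img <- image
  msk <- as_frac_mask(mask)
  pre_key <- paste(p$theta, p$noise_rep, p$eta_x, p$eta_y, p$eta_z, spacing)

  if (!is.na(p$theta)) {
    rt <- rotate_axial(img, msk, p$theta)
    img <- rt$image
    msk <- rt$mask
  }
  if (!is.na(p$noise_rep)) {
    seed_n <- derive_seed(base_seed, chain$label, "noise", p$noise_rep,
                          p$theta)
    img <- add_noise(img, noise_sd, seed = seed_n)
  }
  if (!is.na(p$eta_x)) {
    tr <- translate(img, msk, c(p$eta_x, p$eta_y, p$eta_z))
    img <- tr$image
    msk <- tr$mask
  }
  proc <- interpolate_to_isotropic(img, msk, spacing, config)
  img <- proc$image
  bmask <- proc$mask
  if (!is.na(p$tau) && p$tau != 0) {
    bmask <- adapt_volume(bmask, p$tau)
  }
  if (!is.na(p$contour_rep)) {
    sv <- NULL
    if (!is.null(sv_cache)) {
      if (!exists(pre_key, envir = sv_cache)) {
        assign(pre_key,
               slic_supervoxels(img, chain$supervoxel$target_volume_mm3,
                                chain$supervoxel$compactness),
               envir = sv_cache)
      }
      sv <- get(pre_key, envir = sv_cache)
    }
    seed_c <- derive_seed(base_seed, chain$label, "contour", p$contour_rep,
                          pre_key, p$tau)
    bmask <- contour_randomise(
      img, bmask, seed = seed_c,
      target_volume_mm3 = chain$supervoxel$target_volume_mm3,
      compactness = chain$supervoxel$compactness,
      keep_threshold = chain$supervoxel$keep_threshold,
      supervoxels = sv)
  }
  bmask$kind <- "morphological"
  list(image = img, mask = bmask,
       provenance = list(chain = chain$label, params = as.list(p),
                         spacing = spacing, base_seed = base_seed,
                         noise_sd = noise_sd))
}

#' Replay a perturbed sample from its provenance
#'
#' Reapplies the recorded chain, parameter tuple and seed to the original
#' image and mask, reproducing the sample bit-exactly.
#'
#' @param provenance The `provenance` element of a sample from
#'   [expand_chain()].
#' @param chain The [perturbation_chain()] named by the provenance.
#' @param image,mask Original inputs.
#' @param config A [processing_config()].
#' @return A sample list as from [expand_chain()].
#' @export
replay_sample <- function(provenance, chain, image, mask,
                          config = processing_config()) {
  stopifnot(chain$label == provenance$chain)
  p <- as.data.frame(provenance$params)
  apply_chain_sample(chain, image, as_frac_mask(mask), p, config,
                     provenance$spacing, provenance$base_seed,
                     provenance$noise_sd)
}
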