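#' Feature manifest
#'
#' Enumerates every feature the extractor produces: 182 base features over
#' 11 families, computed at each configured isotropic voxel spacing, with
#' the 118 discretisation-dependent features expanded over every
#' discretisation setting. With the default configuration (4 spacings, 4
#' fixed bin numbers + 4 fixed bin sizes) this yields
#' `64 x 4 + 118 x 4 x 8 = 4032` features.
#'
#' Family composition: morphology (29), local intensity (2), intensity
#' statistics (18) and intensity-volume histogram (15) form the 64
#' non-discretised base features; intensity histogram (23), GLCM (25),
#' GLRLM (16), GLSZM (16), GLDZM (16), NGTDM (5) and NGLDM (17) form the
#' 118 discretisation-dependent ones.
#'
#' @param config A [processing_config()].
#' @return A data frame with one row per expanded feature: `family`,
#'   `name`, `requires_disc`, `spacing`, `disc_method`, `disc_value` and
#'   the unique `id`.
#' @export
build_manifest <- function(config = processing_config()) {
  fam <- family_definitions()
  base <- do.call(rbind, lapply(names(fam), function(f) {
    data.frame(family = f, name = fam[[f]]$names,
               requires_disc = fam[[f]]$disc, stringsAsFactors = FALSE)
  }))
  n_base <- nrow(base)
  n_disc <- sum(base$requires_disc)
  if (n_base != 182L || n_disc != 118L) {
    stop(sprintf("manifest integrity error: %d base / %d discretised",
                 n_base, n_disc))
  }

  disc_settings <- rbind(
    if (length(config$bin_numbers)) {
      data.frame(disc_method = "fixed_bin_number",
                 disc_value = config$bin_numbers)
    },
    if (length(config$bin_sizes)) {
      data.frame(disc_method = "fixed_bin_size",
                 disc_value = config$bin_sizes)
    })
  if (is.null(disc_settings) || nrow(disc_settings) == 0) {
    stop("at least one discretisation setting is required")
  }

  rows <- lapply(config$spacings, function(sp) {
    nd <- base[!base$requires_disc, ]
    nd$spacing <- sp
    nd$disc_method <- NA_character_
    nd$disc_value <- NA_real_
    dd <- do.call(rbind, lapply(seq_len(nrow(disc_settings)), function(s) {
      b <- base[base$requires_disc, ]
      b$spacing <- sp
      b$disc_method <- disc_settings$disc_method[s]
      b$disc_value <- disc_settings$disc_value[s]
      b
    }))
    rbind(nd, dd)
  })
  man <- do.call(rbind, rows)
  man$id <- feature_id(man)
  rownames(man) <- NULL
  if (anyDuplicated(man$id)) stop("manifest integrity error: duplicate ids")
  man
}

family_definitions <- function() {
  list(
    morphological = list(names = morph_feature_names, disc = FALSE),
    local_intensity = list(names = local_intensity_names, disc = FALSE),
    intensity_statistics = list(names = stat_feature_names, disc = FALSE),
    intensity_volume_histogram = list(names = ivh_feature_names,
                                      disc = FALSE),
    intensity_histogram = list(names = ih_feature_names, disc = TRUE),
    glcm = list(names = glcm_feature_names, disc = TRUE),
    glrlm = list(names = glrlm_feature_names, disc = TRUE),
    glszm = list(names = glszm_feature_names, disc = TRUE),
    gldzm = list(names = gldzm_feature_names, disc = TRUE),
    ngtdm = list(names = ngtdm_feature_names, disc = TRUE),
    ngldm = list(names = ngldm_feature_names, disc = TRUE))
}

feature_id <- function(man) {
  disc_tag <- ifelse(is.na(man$disc_method), "",
                     paste0("_", ifelse(man$disc_method == "fixed_bin_number",
                                        "fbn", "fbs"),
                            man$disc_value))
  paste0(man$family, "_", man$name, "_", man$spacing, "mm", disc_tag)
}

#' Compute features for one processed image
#'
#' Evaluates every descriptor of (a subset of) the manifest on an image that
#' has already been interpolated to one isotropic spacing, with its
#' morphological and intensity masks. Morphology uses the morphological
#' mask; all intensity and texture families use the intensity mask.
#' Features whose value is undefined on the input (degenerate ROIs) are
#' returned as `NA` rather than an error.
#'
#' @param image Processed [vol_image()].
#' @param morph_mask Morphological [roi_mask()].
#' @param int_mask Intensity [roi_mask()] (subset of `morph_mask`).
#' @param manifest Manifest rows for this spacing (see [build_manifest()]).
#' @param config A [processing_config()].
#' @return Named numeric vector, one element per manifest row (names =
#'   feature ids).
#' @export
compute_features <- function(image, morph_mask, int_mask, manifest,
                             config = processing_config()) {
  vals <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$id)
  x <- image$voxels[int_mask$labels]

  fill <- function(family, fvals, rows) {
    key <- paste0(family, "_", names(fvals))
    hit <- match(paste0(rows$family, "_", rows$name), key)
    vals[rows$id] <<- fvals[hit]
  }

  for (family in unique(manifest$family[is.na(manifest$disc_method)])) {
    rows <- manifest[manifest$family == family &
                     is.na(manifest$disc_method), ]
    fvals <- switch(family,
      morphological = morph_features(image, morph_mask, int_mask),
      local_intensity = local_intensity_features(image, int_mask),
      intensity_statistics = stat_features(x),
      intensity_volume_histogram = ivh_features(x, config))
    fill(family, fvals, rows)
  }

  disc_rows <- manifest[!is.na(manifest$disc_method), ]
  if (nrow(disc_rows) > 0) {
    settings <- unique(disc_rows[, c("disc_method", "disc_value")])
    for (s in seq_len(nrow(settings))) {
      mth <- settings$disc_method[s]
      val <- settings$disc_value[s]
      grid <- level_grid(image, int_mask, mth, val, config)
      nl <- attr(grid, "n_levels")
      sub <- disc_rows[disc_rows$disc_method == mth &
                       disc_rows$disc_value == val, ]
      for (family in unique(sub$family)) {
        rows <- sub[sub$family == family, ]
        fvals <- switch(family,
          intensity_histogram = ih_features(grid[int_mask$labels], nl),
          glcm = glcm_features(grid, nl),
          glrlm = glrlm_features(grid, nl),
          glszm = glszm_features(grid, nl),
          gldzm = gldzm_features(grid, nl, morph_mask),
          ngtdm = ngtdm_features(grid, nl),
          ngldm = ngldm_features(grid, nl))
        fill(family, fvals, rows)
      }
    }
  }
  vals
}

#' Extract all manifest features from an unprocessed image and mask
#'
#' Runs the full processing per spacing (isotropic interpolation with
#' anti-aliasing, HU rounding, partial-volume mask thresholding,
#' re-segmentation) and computes every manifest feature.
#'
#' @param image A [vol_image()] on its native grid.
#' @param mask A [roi_mask()] or [frac_mask()] on the same grid.
#' @param config A [processing_config()].
#' @param manifest Optional manifest (defaults to `build_manifest(config)`).
#' @return Named numeric vector over the whole manifest.
#' @export
extract_features <- function(image, mask, config = processing_config(),
                             manifest = NULL) {
  if (is.null(manifest)) manifest <- build_manifest(config)
  vals <- stats::setNames(rep(NA_real_, nrow(manifest)), manifest$id)
  for (sp in unique(manifest$spacing)) {
    sub <- manifest[manifest$spacing == sp, ]
    res <- tryCatch({
      proc <- interpolate_to_isotropic(image, mask, sp, config)
      morph <- proc$mask
      morph$kind <- "morphological"
      int <- resegment(proc$image, morph, config)
      compute_features(proc$image, morph, int, sub, config)
    }, error = function(e) NULL)
    if (!is.null(res)) vals[sub$id] <- res
  }
  vals
}
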