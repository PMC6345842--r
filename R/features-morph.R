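# Morphological feature family (29 features). Shape descriptors are
# computed from the morphological mask: mesh volume/area from marching
# tetrahedra, principal-axis descriptors from the voxel-centre covariance,
# and density descriptors against axis-aligned / oriented bounding boxes,
# enclosing ellipsoids and the convex hull. Integrated intensity and the
# spatial autocorrelation measures additionally use the image restricted to
# the intensity mask.

morph_feature_names <- c(
  "volume_mesh", "volume_voxel", "surface_area", "surface_volume_ratio",
  "compactness_1", "compactness_2", "spherical_disproportion", "sphericity",
  "asphericity", "com_shift", "max_diameter", "major_axis", "minor_axis",
  "least_axis", "elongation", "flatness", "vol_density_aabb",
  "area_density_aabb", "vol_density_ombb", "area_density_ombb",
  "vol_density_aee", "area_density_aee", "vol_density_mvee",
  "area_density_mvee", "vol_density_chull", "area_density_chull",
  "integrated_intensity", "morans_i", "gearys_c")

morph_features <- function(image, morph_mask, int_mask) {
  out <- stats::setNames(rep(NA_real_, length(morph_feature_names)),
                         morph_feature_names)
  nvox <- mask_volume(morph_mask)
  if (nvox == 0) return(out)
  sp <- morph_mask$spacing

  mesh <- mesh_surface_stats(morph_mask)
  V <- mesh$volume
  A <- mesh$area
  out["volume_mesh"] <- V
  out["volume_voxel"] <- nvox * prod(sp)
  out["surface_area"] <- A
  if (V > 0 && A > 0) {
    out["surface_volume_ratio"] <- A / V
    out["compactness_1"] <- V / (sqrt(pi) * A^1.5)
    out["compactness_2"] <- 36 * pi * V^2 / A^3
    out["spherical_disproportion"] <- A / (36 * pi * V^2)^(1 / 3)
    out["sphericity"] <- (36 * pi * V^2)^(1 / 3) / A
    out["asphericity"] <- (A^3 / (36 * pi * V^2))^(1 / 3) - 1
  }

  # centre-of-mass shift between geometric (morphological) and
  # intensity-weighted (intensity mask) centres
  idxm <- which(morph_mask$labels, arr.ind = TRUE)
  ptsm <- sweep(sweep(idxm - 1, 2, sp, "*"), 2, morph_mask$origin, "+")
  com_geom <- colMeans(ptsm)
  vi <- image$voxels[int_mask$labels]
  if (length(vi) > 0) {
    idxi <- which(int_mask$labels, arr.ind = TRUE)
    ptsi <- sweep(sweep(idxi - 1, 2, sp, "*"), 2, int_mask$origin, "+")
    # weights shifted to be positive (HU can be negative)
    w <- vi - min(vi) + 1
    com_int <- colSums(ptsi * w) / sum(w)
    out["com_shift"] <- sqrt(sum((com_geom - com_int)^2))
  }

  # principal axes from the voxel-centre covariance
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(ptsm), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    out["major_axis"] <- 4 * sqrt(ev[1])
    out["minor_axis"] <- 4 * sqrt(ev[2])
    out["least_axis"] <- 4 * sqrt(ev[3])
    out["elongation"] <- sqrt(ev[2] / ev[1])
    out["flatness"] <- sqrt(ev[3] / ev[1])
  }

  # bounding boxes and enclosing shapes
  aabb <- mesh$bb_max - mesh$bb_min
  if (all(is.finite(aabb)) && all(aabb > 0)) {
    out["vol_density_aabb"] <- V / prod(aabb)
    out["area_density_aabb"] <- A / (2 * (aabb[1] * aabb[2] +
                                          aabb[1] * aabb[3] +
                                          aabb[2] * aabb[3]))
  }
  surf_pts <- surface_voxel_centres(morph_mask)
  if (nrow(surf_pts) >= 4 && nvox > 1) {
    # oriented bounding box approximated in the principal-axis frame
    eg <- eigen(stats::cov(ptsm), symmetric = TRUE)
    proj <- sweep(ptsm, 2, com_geom) %*% eg$vectors
    ombb <- apply(proj, 2, function(cc) diff(range(cc))) + 0  # mm extents
    ombb <- pmax(ombb, min(sp))
    out["vol_density_ombb"] <- V / prod(ombb)
    out["area_density_ombb"] <- A / (2 * (ombb[1] * ombb[2] +
                                          ombb[1] * ombb[3] +
                                          ombb[2] * ombb[3]))
    # axis-aligned (principal-frame) enclosing ellipsoid from PCA
    semi <- 2 * sqrt(pmax(eg$values, 0))
    if (all(semi > 0)) {
      out["vol_density_aee"] <- V / (4 / 3 * pi * prod(semi))
      out["area_density_aee"] <- A / ellipsoid_area(sort(semi,
                                                         decreasing = TRUE))
    }
    hull <- convex_hull_3d(surf_pts)
    if (!is.null(hull)) {
      out["vol_density_chull"] <- V / hull$volume
      out["area_density_chull"] <- A / hull$area
      hv <- hull$vertices
      out["max_diameter"] <- sqrt(max(as.matrix(stats::dist(hv))^2))
      mv <- mvee_semiaxes(hv)
      if (!is.null(mv)) {
        out["vol_density_mvee"] <- V / (4 / 3 * pi * prod(mv))
        out["area_density_mvee"] <- A / ellipsoid_area(mv)
      }
    }
  } else if (nrow(surf_pts) >= 2) {
    out["max_diameter"] <- sqrt(max(as.matrix(stats::dist(surf_pts))^2))
  } else {
    out["max_diameter"] <- 0
  }

  if (length(vi) > 0) {
    out["integrated_intensity"] <- mean(vi) * V
    ac <- spatial_autocorrelation(image, int_mask)
    out["morans_i"] <- ac$moran
    out["gearys_c"] <- ac$geary
  }
  out
}

# Moran's I and Geary's C over the intensity mask with inverse-distance
# weights. For large ROIs a deterministic subsample (evenly spaced in array
# order) of at most `max_n` voxels keeps the O(n^2) pair sums tractable.
spatial_autocorrelation <- function(image, int_mask, max_n = 600) {
  idx <- which(int_mask$labels)
  n <- length(idx)
  if (n < 3) return(list(moran = NA_real_, geary = NA_real_))
  if (n > max_n) {
    idx <- idx[unique(round(seq(1, n, length.out = max_n)))]
    n <- length(idx)
  }
  d <- dim(int_mask$labels)
  ar <- arrayInd(idx, d)
  pts <- sweep(sweep(ar - 1, 2, int_mask$spacing, "*"), 2,
               int_mask$origin, "+")
  x <- image$voxels[idx]
  mu <- mean(x)
  dev <- x - mu
  denom <- sum(dev^2)
  if (denom == 0) return(list(moran = NA_real_, geary = NA_real_))
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  w <- 1 / dm
  s0 <- sum(w)
  moran <- (n / s0) * sum(w * outer(dev, dev)) / denom
  geary <- ((n - 1) / (2 * s0)) * sum(w * outer(x, x, "-")^2) / denom
  list(moran = moran, geary = geary)
}
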