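# Low-level resampling primitives shared by the perturbation operators and
# the isotropic interpolation step: separable Gaussian smoothing and
# vectorised trilinear sampling at arbitrary physical coordinates.

# Separable Gaussian blur with per-axis sigma in voxel units. Axes with
# sigma <= 0 are left untouched. Borders use edge replication so constant
# images stay exactly constant.
gaussian_blur <- function(vox, sigma_vox) {
  d <- dim(vox)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (!is.finite(s) || s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    vox <- convolve_axis(vox, k, ax)
  }
  vox
}

# 1D convolution along one axis of a 3D array with edge replication.
convolve_axis <- function(vox, kernel, axis) {
  d <- dim(vox)
  r <- (length(kernel) - 1L) / 2L
  n <- d[axis]
  out <- array(0, dim = d)
  idx_base <- seq_len(n)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    src <- pmin(pmax(idx_base + off, 1L), n)
    out <- out + kernel[t] * index_axis(vox, src, axis)
  }
  out
}

# reorder an array along one axis by the index vector `src`
index_axis <- function(vox, src, axis) {
  switch(axis,
         vox[src, , , drop = FALSE],
         vox[, src, , drop = FALSE],
         vox[, , src, drop = FALSE])
}

# Trilinear sampling of `vox` at continuous 1-based index coordinates
# (matrix n x 3). Coordinates within 1e-6 of an integer are snapped so that
# identity transforms reproduce voxels bit-exactly. `outside`: "clamp"
# replicates the nearest edge voxel, a number fills with that constant.
trilinear_sample <- function(vox, idx, outside = "clamp") {
  d <- dim(vox)
  snap <- round(idx)
  near <- abs(idx - snap) < 1e-6
  idx[near] <- snap[near]

  fill_const <- !identical(outside, "clamp")
  if (fill_const) {
    oob <- idx[, 1] < 1 | idx[, 1] > d[1] |
           idx[, 2] < 1 | idx[, 2] > d[2] |
           idx[, 3] < 1 | idx[, 3] > d[3]
  }
  i0 <- pmin(pmax(floor(idx[, 1]), 1), d[1])
  j0 <- pmin(pmax(floor(idx[, 2]), 1), d[2])
  k0 <- pmin(pmax(floor(idx[, 3]), 1), d[3])
  fx <- pmin(pmax(idx[, 1] - i0, 0), 1)
  fy <- pmin(pmax(idx[, 2] - j0, 0), 1)
  fz <- pmin(pmax(idx[, 3] - k0, 0), 1)
  i1 <- pmin(i0 + 1, d[1])
  j1 <- pmin(j0 + 1, d[2])
  k1 <- pmin(k0 + 1, d[3])

  at <- function(ii, jj, kk) vox[cbind(ii, jj, kk)]
  val <-
    at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1, j0, k0) * fx       * (1 - fy) * (1 - fz) +
    at(i0, j1, k0) * (1 - fx) * fy       * (1 - fz) +
    at(i1, j1, k0) * fx       * fy       * (1 - fz) +
    at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    at(i1, j0, k1) * fx       * (1 - fy) * fz +
    at(i0, j1, k1) * (1 - fx) * fy       * fz +
    at(i1, j1, k1) * fx       * fy       * fz
  if (fill_const) val[oob] <- as.numeric(outside)
  val
}

# Physical coordinates (n x 3 matrix) of every voxel centre of a grid.
grid_centres <- function(dims, spacing, origin) {
  xs <- axis_coords(dims[1], spacing[1], origin[1])
  ys <- axis_coords(dims[2], spacing[2], origin[2])
  zs <- axis_coords(dims[3], spacing[3], origin[3])
  cbind(rep(xs, times = dims[2] * dims[3]),
        rep(rep(ys, each = dims[1]), times = dims[3]),
        rep(zs, each = dims[1] * dims[2]))
}

# physical mm -> continuous 1-based index coordinates
phys_to_index <- function(pts, spacing, origin) {
  cbind((pts[, 1] - origin[1]) / spacing[1] + 1,
        (pts[, 2] - origin[2]) / spacing[2] + 1,
        (pts[, 3] - origin[3]) / spacing[3] + 1)
}
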