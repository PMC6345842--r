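test_that("NIfTI write/read round-trips voxels, spacing and origin exactly", {
  ph <- sphere_phantom(shape = c(20, 20, 14), spacing = c(0.5, 1, 2),
                       radii = 4, noise = 7, seed = 3)
  path <- tempfile(fileext = ".nii.gz")
  write_nifti(ph$image, path)
  back <- read_image(path)
  expect_identical(back$voxels, ph$image$voxels)
  expect_identical(back$spacing, ph$image$spacing)
  expect_identical(back$origin, ph$image$origin)

  # masks round-trip through the same writer
  mpath <- tempfile(fileext = ".nii.gz")
  write_nifti(ph$mask, mpath)
  mback <- read_mask(mpath)
  expect_identical(mback$labels, ph$mask$labels)
})

test_that("read_image rejects missing files and DICOM series input", {
  expect_error(read_image(tempfile(fileext = ".nii")), "not found")
  expect_error(read_image(tempfile(), format = "dicom-series"),
               "not supported")
})

test_that("image and mask constructors enforce their invariants", {
  expect_error(vol_image(array(1, dim = c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(vol_image(array(1, dim = c(4, 4, 4)), c(1, -1, 1)),
               "positive")
  bad <- array(1, dim = c(4, 4, 4))
  bad[2, 2, 2] <- NaN
  expect_error(vol_image(bad), "finite")
  expect_error(roi_mask(array(NA, dim = c(2, 2, 2))), "NA")
})

test_that("polygon rasterisation follows the voxel-centre even-odd rule", {
  grid <- vol_image(array(0, dim = c(6, 6, 3)))
  # square covering exactly the centres of a 2x2 voxel patch on slice z=1
  sq <- list(cbind(c(0.9, 2.1, 2.1, 0.9), c(0.9, 0.9, 2.1, 2.1), 1))
  m <- rasterise_contours(sq, grid)
  expect_equal(mask_volume(m), 4)
  expect_true(all(which(m$labels, arr.ind = TRUE)[, 3] == 2))

  # same square shrunk to exclude all voxel centres -> empty-mask error
  tiny <- list(cbind(c(1.2, 1.8, 1.8, 1.2), c(1.2, 1.2, 1.8, 1.8), 1))
  expect_error(rasterise_contours(tiny, grid), "empty")

  # polygon plane must match a slice
  far <- list(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2), 9.7))
  expect_error(rasterise_contours(far, grid), "no grid slice")

  expect_error(rasterise_contours(list(), grid), "empty polygon set")
})

test_that("digital circle rasterisation approximates the analytic area", {
  grid <- vol_image(array(0, dim = c(30, 30, 1)))
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- list(cbind(14.5 + 10 * cos(th), 14.5 + 10 * sin(th), 0))
  m <- rasterise_contours(circ, grid)
  expect_lt(abs(mask_volume(m) - pi * 100) / (pi * 100), 0.05)
})

test_that("rasterisation agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  grid <- vol_image(array(0, dim = c(15, 15, 1)))
  for (seed in 1:5) {
    set.seed(seed)
    pts <- cbind(runif(12, 1, 13), runif(12, 1, 13))
    hull <- grDevices::chull(pts)
    poly <- pts[hull, , drop = FALSE]
    m <- rasterise_contours(list(cbind(poly, 0)), grid)
    centres <- as.matrix(expand.grid(x = 0:14, y = 0:14))
    # mgcv uses a different crossing implementation; boundary-exact points
    # may legitimately differ, so test points off the boundary only
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), centres)
    expect_equal(as.vector(m$labels[, , 1]), inside)
  }
})

test_that("phantom mask matches the analytic sphere by the voxel-centre rule", {
  ph <- sphere_phantom(radii = 10, spacing = 1)
  expect_lt(abs(mask_volume(ph$mask) - 4 / 3 * pi * 1000) /
            (4 / 3 * pi * 1000), 0.03)
})

test_that("phantom generation is a pure function of its spec", {
  spec <- phantom_spec(shape = c(24, 24, 24), radii = 8, noise_sd = 12,
                       foreground = "texture", seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
})

test_that("phantom noise has the requested standard deviation", {
  spec0 <- phantom_spec(shape = c(64, 64, 64), radii = 20, noise_sd = 0)
  spec <- phantom_spec(shape = c(64, 64, 64), radii = 20, noise_sd = 20,
                       seed = 5)
  clean <- generate_phantom(spec0)$image$voxels
  noisy <- generate_phantom(spec)$image$voxels
  expect_gt(sd(noisy - clean), 18)
  expect_lt(sd(noisy - clean), 22)
})

test_that("phantom spec validates geometry and round-trips through YAML", {
  expect_error(phantom_spec(shape = c(16, 16, 16), radii = 20),
               "fit inside")
  spec <- phantom_spec(shape = c(20, 20, 20), radii = 6, noise_sd = 4,
                       foreground = "texture", seed = 9)
  path <- tempfile(fileext = ".yaml")
  phantom_spec_to_yaml(spec, path)
  back <- phantom_spec_from_yaml(path)
  expect_equal(unclass(back), unclass(spec))
  expect_identical(generate_phantom(back)$image$voxels,
                   generate_phantom(spec)$image$voxels)
})
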