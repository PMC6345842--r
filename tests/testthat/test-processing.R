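test_that("interpolation at the native spacing is the identity", {
  ph <- textured_phantom(seed = 5, spacing = 3)
  out <- interpolate_to_isotropic(ph$image, ph$mask, 3,
                                  processing_config(spacings = 3))
  expect_identical(out$image$voxels, round(ph$image$voxels))
  expect_identical(out$mask$labels, ph$mask$labels)
})

test_that("interpolation of a constant image is exact at any spacing", {
  img <- vol_image(array(40, dim = c(20, 20, 20)), spacing = c(1, 1, 1))
  msk <- roi_mask(array(TRUE, dim = c(20, 20, 20)))
  for (sp in c(0.7, 2, 3.3)) {
    out <- interpolate_to_isotropic(img, msk, sp, processing_config())
    expect_true(all(out$image$voxels == 40))
  }
})

test_that("upsampling a linear ramp reproduces the analytic field", {
  # 2 mm source, 1 mm target: upsampling, so no anti-alias smoothing; the
  # ramp is affine so trilinear interpolation is exact before rounding
  d <- c(12, 10, 10)
  ramp <- vol_image(array(rep(seq(0, 110, by = 10), times = 100), dim = d),
                    spacing = c(2, 2, 2))
  msk <- roi_mask(array(TRUE, dim = d), spacing = c(2, 2, 2))
  out <- interpolate_to_isotropic(ramp, msk, 1, processing_config())
  centres <- out$image$origin[1] +
    (seq_len(dim(out$image$voxels)[1]) - 1) * out$image$spacing[1]
  expected <- floor(5 * centres + 0.5)  # ramp 5 HU/mm, half away from zero
  interior <- centres >= 0 & centres <= 22
  expect_equal(out$image$voxels[interior, 5, 5], expected[interior])
})

test_that("interpolation errors on masks that vanish", {
  ph <- sphere_phantom(shape = c(20, 20, 20), radii = 1.0, spacing = 1,
                       centre = c(2.5, 2.5, 2.5))
  expect_error(interpolate_to_isotropic(ph$image, ph$mask, 8,
                                        processing_config()),
               "empty")
})

test_that("mask binarisation is monotone in the threshold", {
  ph <- textured_phantom(seed = 7)
  rot <- rotate_axial(ph$image, ph$mask, 9)
  lo <- binarise_mask(rot$mask, 0.3)
  hi <- binarise_mask(rot$mask, 0.7)
  expect_true(all(lo$labels[hi$labels]))  # raising threshold never adds
  expect_lte(mask_volume(hi), mask_volume(lo))
})

test_that("re-segmentation applies the HU window then the sigma rule", {
  d <- c(10, 10, 10)
  vox <- array(40, dim = d)
  msk <- roi_mask(array(TRUE, dim = d))
  cfg <- processing_config(resegment_range = c(-300, 200))

  # constant ROI: intensity mask equals the morphological mask
  int <- resegment(vol_image(vox), msk, cfg)
  expect_identical(int$labels, msk$labels)
  expect_equal(int$kind, "intensity")

  # an air voxel inside the ROI is outside [-300, 200] and is excluded
  vox_air <- vox
  vox_air[5, 5, 5] <- -1000
  int2 <- resegment(vol_image(vox_air), msk, cfg)
  expect_false(int2$labels[5, 5, 5])
  expect_equal(mask_volume(int2), prod(d) - 1)

  # a +100 outlier in a N(0, 10) ROI fails the 3-sigma rule
  set.seed(1)
  vox_out <- array(rnorm(prod(d), 0, 10), dim = d)
  vox_out[2, 2, 2] <- 100
  int3 <- resegment(vol_image(vox_out), msk, cfg)
  expect_false(int3$labels[2, 2, 2])

  # the morphological mask itself is untouched
  expect_identical(msk$labels, array(TRUE, dim = d))
})

test_that("intensity mask is always a subset of the morphological mask", {
  for (seed in 1:3) {
    ph <- textured_phantom(seed = seed, noise = 15)
    cfg <- processing_config(resegment_range = c(0, 80))
    int <- resegment(ph$image, ph$mask, cfg)
    expect_true(all(ph$mask$labels[int$labels]))
  }
})

test_that("fixed-bin-number discretisation follows the IBSI mapping", {
  cfg <- processing_config()
  expect_equal(as.integer(discretise(c(0, 63.9, 64), "fixed_bin_number", 8,
                                     cfg)),
               c(1L, 8L, 8L))
  # constant ROI maps to level 1
  g <- discretise(rep(55, 10), "fixed_bin_number", 16, cfg)
  expect_true(all(g == 1L))
  # levels always within [1, N]
  set.seed(2)
  x <- rnorm(500, 20, 40)
  g2 <- discretise(x, "fixed_bin_number", 32, cfg)
  expect_gte(min(g2), 1L)
  expect_lte(max(g2), 32L)
  expect_equal(max(g2), 32L)  # the maximum always lands in the top bin
})

test_that("fixed-bin-size discretisation anchors at the range minimum", {
  cfg <- processing_config(resegment_range = c(-150, 180))
  expect_equal(as.integer(discretise(-137, "fixed_bin_size", 6, cfg)), 3L)
  expect_equal(as.integer(discretise(-150, "fixed_bin_size", 6, cfg)), 1L)
  x <- seq(-150, 180, by = 1)
  g <- discretise(x, "fixed_bin_size", 12, cfg)
  expect_gte(min(g), 1L)
  expect_lte(max(g), ceiling((180 - (-150)) / 12))
})

test_that("half-HU intensities round away from zero", {
  img <- vol_image(array(c(0.5, -0.5, 1.5, -1.5, 2.4, -2.4, 0, 1),
                         dim = c(2, 2, 2)))
  msk <- roi_mask(array(TRUE, dim = c(2, 2, 2)))
  out <- interpolate_to_isotropic(img, msk, 1, processing_config())
  expect_equal(as.vector(out$image$voxels),
               c(1, -1, 2, -2, 2, -2, 0, 1))
})
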