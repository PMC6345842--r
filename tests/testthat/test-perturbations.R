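test_that("identity parameters are exact no-ops on image and mask", {
  ph <- textured_phantom(seed = 2)
  r <- rotate_axial(ph$image, ph$mask, 0)
  expect_identical(r$image$voxels, ph$image$voxels)
  expect_identical(r$mask$values, as_frac_mask(ph$mask)$values)
  t <- translate(ph$image, ph$mask, c(0, 0, 0))
  expect_identical(t$image$voxels, ph$image$voxels)
  expect_identical(t$mask$values, as_frac_mask(ph$mask)$values)
  expect_identical(add_noise(ph$image, 0)$voxels, ph$image$voxels)
  expect_identical(adapt_volume(ph$mask, 0)$labels, ph$mask$labels)
})

test_that("90-degree rotation equals the index-permutation oracle", {
  ph <- sphere_phantom(shape = c(30, 30, 12), radii = 5, spacing = 1,
                       foreground = "texture", noise = 10, seed = 4)
  r <- rotate_axial(ph$image, ph$mask, 90, centre = "image")
  # +90 degrees about the grid centre maps (x, y) -> (-y, x); on a square
  # isotropic grid that is a pure array permutation
  d <- dim(ph$image$voxels)
  oracle <- aperm(ph$image$voxels[, d[2]:1, , drop = FALSE], c(2, 1, 3))
  expect_equal(r$image$voxels, oracle, tolerance = 1e-12)
})

test_that("rotating a uniform sphere leaves the ROI mean almost unchanged", {
  # uniform intensity across the whole field: trilinear interpolation of a
  # constant is constant, so only mask re-thresholding could move the mean
  ph <- sphere_phantom(shape = c(36, 36, 36), radii = 12, fg = 40,
                       background = 40)
  r <- rotate_axial(ph$image, ph$mask, 13)
  m <- binarise_mask(r$mask, 0.5)
  mean0 <- mean(ph$image$voxels[ph$mask$labels])
  mean1 <- mean(r$image$voxels[m$labels])
  expect_lt(abs(mean1 - mean0), 0.5)
})

test_that("rotation moving the ROI off the grid raises a coverage error", {
  ph <- sphere_phantom(shape = c(24, 24, 8), radii = 3,
                       centre = c(4, 4, 3.5))
  expect_error(rotate_axial(ph$image, ph$mask, 180, centre = c(60, 60)),
               "outside the grid")
})

test_that("noise SD estimation recovers sigma and ignores structure", {
  base <- vol_image(array(100, dim = c(20, 20, 20)))
  noisy <- add_noise(base, 20, seed = 8)
  est <- estimate_noise_sd(noisy, body_threshold = NULL)
  expect_gt(est, 17)
  expect_lt(est, 23)

  expect_warning(est0 <- estimate_noise_sd(base, body_threshold = NULL),
                 "constant")
  expect_equal(est0, 0)

  ramp <- vol_image(array(rep(seq(0, 300, length.out = 20), times = 400),
                          dim = c(20, 20, 20)))
  expect_lt(estimate_noise_sd(ramp, body_threshold = NULL), 2)
  # a naive SD would see the ramp as huge "noise"
  expect_gt(sd(ramp$voxels), 50)
})

test_that("add_noise has the right moments and is seed-deterministic", {
  base <- vol_image(array(0, dim = c(64, 64, 64)))
  noisy <- add_noise(base, 15, seed = 21)
  diff <- noisy$voxels - base$voxels
  expect_lt(abs(mean(diff)), 0.5)
  expect_gt(sd(diff), 14.5)
  expect_lt(sd(diff), 15.5)
  expect_identical(add_noise(base, 15, seed = 21)$voxels, noisy$voxels)
  expect_false(identical(add_noise(base, 15, seed = 22)$voxels,
                         noisy$voxels))
  expect_error(add_noise(base, -1), ">= 0")
})

test_that("sub-voxel translation interpolates a linear ramp exactly", {
  d <- c(20, 12, 12)
  ramp <- vol_image(array(rep(1:20, times = 144), dim = d))
  msk <- roi_mask(array(TRUE, dim = d))
  t <- translate(ramp, msk, c(0.5, 0, 0))
  interior <- t$image$voxels[2:19, , ]
  expected <- (ramp$voxels[1:18, , ] + ramp$voxels[2:19, , ]) / 2
  expect_equal(interior, expected, tolerance = 1e-12)
  expect_error(translate(ramp, msk, c(1, 0, 0)), "\\[0, 1\\)")
})

test_that("two half-voxel shifts of an affine field equal an index shift", {
  d <- c(16, 16, 8)
  ramp <- vol_image(array(rep(1:16, times = 128), dim = d))
  msk <- roi_mask(array(TRUE, dim = d))
  once <- translate(ramp, msk, c(0.5, 0, 0))
  twice <- translate(once$image, once$mask, c(0.5, 0, 0))
  # interior voxels away from the clamped edge
  expect_equal(twice$image$voxels[3:16, , ], ramp$voxels[2:15, , ],
               tolerance = 1e-12)
})

test_that("translation fractions permute to m^3 per-axis tuples", {
  expect_equal(nrow(permute_translations(c(0.25, 0.5))), 8)
  expect_equal(nrow(permute_translations(0)), 1)
  expect_equal(nrow(permute_translations(c(0.25, 0.5, 0.75))), 27)
  expect_error(permute_translations(numeric(0)), "empty")
})

test_that("volume adaptation hits the target count and nests correctly", {
  ph <- sphere_phantom(radii = 10, spacing = 1)
  n0 <- mask_volume(ph$mask)
  grown <- adapt_volume(ph$mask, 0.28)
  expect_lt(abs(mask_volume(grown) - 1.28 * n0) / (1.28 * n0), 0.02)
  expect_true(all(grown$labels[ph$mask$labels]))  # superset
  shrunk <- adapt_volume(ph$mask, -0.28)
  expect_lt(abs(mask_volume(shrunk) - 0.72 * n0) / (0.72 * n0), 0.02)
  expect_true(all(ph$mask$labels[shrunk$labels]))  # subset
  expect_error(adapt_volume(ph$mask, 1.2), "tau")
  one <- roi_mask(array(c(TRUE, rep(FALSE, 7)), dim = c(2, 2, 2)))
  expect_error(adapt_volume(one, -0.9), "eliminate")
})

test_that("SLIC supervoxels partition the volume deterministically", {
  ph <- textured_phantom(seed = 6, shape = c(14, 14, 14))
  sv <- slic_supervoxels(ph$image, target_volume_mm3 = 400)
  expect_true(all(sv >= 1))
  expect_identical(dim(sv), dim(ph$image$voxels))
  expect_gt(length(unique(as.vector(sv))), 8)
  expect_identical(slic_supervoxels(ph$image, target_volume_mm3 = 400), sv)
})

test_that("contour randomisation perturbs the rim but keeps the gross shape", {
  ph <- sphere_phantom(shape = c(36, 36, 36), radii = 10, fg = 40,
                       noise = 20, seed = 3)
  sv <- slic_supervoxels(ph$image, target_volume_mm3 = 150)
  dice <- vapply(1:100, function(s) {
    m <- contour_randomise(ph$image, ph$mask, seed = s, supervoxels = sv)
    2 * sum(m$labels & ph$mask$labels) /
      (sum(m$labels) + sum(ph$mask$labels))
  }, numeric(1))
  expect_gte(median(dice), 0.80)
  expect_lt(median(dice), 1.0)
  m1 <- contour_randomise(ph$image, ph$mask, seed = 42, supervoxels = sv)
  m2 <- contour_randomise(ph$image, ph$mask, seed = 42, supervoxels = sv)
  expect_identical(m1$labels, m2$labels)
  expect_error(contour_randomise(ph$image, ph$mask, seed = 1,
                                 target_volume_mm3 = 1e6),
               "exceeds the ROI volume")
})

test_that("chain expansion size is the product of the parameter grids", {
  ph <- textured_phantom(seed = 1)
  cfg <- processing_config(spacings = 3)
  n30 <- expand_chain(perturbation_chain("N", noise_reps = 30),
                      ph$image, ph$mask, cfg, spacing = 3, base_seed = 5)
  expect_length(n30, 30)
  t8 <- expand_chain(perturbation_chain("T", translations = c(0.25, 0.5)),
                     ph$image, ph$mask, cfg, spacing = 3, base_seed = 5)
  expect_length(t8, 8)
  rv <- expand_chain(
    perturbation_chain("RV", angles = c(-10, 0, 10),
                       taus = c(-0.2, -0.1, 0, 0.1, 0.2)),
    ph$image, ph$mask, cfg, spacing = 3, base_seed = 5)
  expect_length(rv, 15)
})

test_that("the default registry reproduces the published per-chain counts", {
  reg <- default_chain_registry()
  expect_length(reg, 18)
  expected <- c(R = 27, N = 30, T = 27, V = 29, C = 30, RT = 32, RNT = 32,
                RV = 30, RC = 27, TV = 40, TC = 27, RTC = 32, RNTC = 32,
                VC = 30, RVC = 30, RNVC = 30, TVC = 40, NTVC = 40)
  expect_equal(vapply(reg[names(expected)], chain_size, integer(1)),
               expected, ignore_attr = FALSE)
})

test_that("each operator touches only what it should", {
  ph <- textured_phantom(seed = 9)
  # noise: image only (mask is not even an argument)
  noisy <- add_noise(ph$image, 5, seed = 1)
  expect_false(identical(noisy$voxels, ph$image$voxels))
  # V and C: mask only (image is unchanged by construction)
  grown <- adapt_volume(ph$mask, 0.2)
  expect_false(identical(grown$labels, ph$mask$labels))
  # R and T: both image and mask
  r <- rotate_axial(ph$image, ph$mask, 7)
  expect_false(identical(r$image$voxels, ph$image$voxels))
  expect_false(identical(r$mask$values, as_frac_mask(ph$mask)$values))
  t <- translate(ph$image, ph$mask, c(0.25, 0.25, 0))
  expect_false(identical(t$image$voxels, ph$image$voxels))
  expect_false(identical(t$mask$values, as_frac_mask(ph$mask)$values))
})

test_that("samples replay bit-exactly from their provenance", {
  ph <- textured_phantom(seed = 3)
  cfg <- processing_config(spacings = 3)
  chain <- perturbation_chain("RNVC", angles = c(-8, 8), noise_reps = 1,
                              taus = c(-0.14, 0.14), contour_reps = 2)
  samples <- expand_chain(chain, ph$image, ph$mask, cfg, spacing = 3,
                          base_seed = 17)
  expect_length(samples, 8)
  for (s in samples[c(1, 5, 8)]) {
    again <- replay_sample(s$provenance, chain, ph$image, ph$mask, cfg)
    expect_identical(again$image$voxels, s$image$voxels)
    expect_identical(again$mask$labels, s$mask$labels)
  }
})
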