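# Shared fixture builders: all fixtures are generated in code so the test
# suite needs no data files.

sphere_phantom <- function(shape = c(36, 36, 36), radii = 10, spacing = 1,
                           fg = 40, noise = 0, seed = 1,
                           foreground = "constant", ...) {
  generate_phantom(phantom_spec(shape = shape, spacing = spacing,
                                radii = radii, fg_value = fg,
                                noise_sd = noise, seed = seed,
                                foreground = foreground, ...))
}

# small textured phantom for texture/pipeline tests (coarse grid, fast)
textured_phantom <- function(seed = 1, shape = c(16, 16, 16), spacing = 3,
                             radii = 12, noise = 3) {
  generate_phantom(phantom_spec(shape = shape, spacing = spacing,
                                radii = radii, fg_value = 40,
                                foreground = "texture", fg_range = 40,
                                fg_levels = 8, noise_sd = noise,
                                seed = seed))
}

# random small discretised grid (0 = outside ROI) for texture-matrix oracles
random_level_grid <- function(seed, dims = c(6, 6, 6), n_levels = 4,
                              p_roi = 0.8) {
  set.seed(seed)
  g <- array(0L, dim = dims)
  roi <- array(runif(prod(dims)) < p_roi, dim = dims)
  g[roi] <- sample.int(n_levels, sum(roi), replace = TRUE)
  g
}
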