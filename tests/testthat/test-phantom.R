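test_that("expression profiles evaluate their closed forms", {
  # K = 0 decay is constant at y0
  s <- profile_spec("one_phase_decay", plateau = 0, y0 = 1, K = 0)
  expect_equal(sample_expression(17, s), 1.0)
  # plateau + span * exp(-K x)
  s <- profile_spec("one_phase_decay", plateau = 0.2, y0 = 1.0, K = 0.1)
  expect_equal(sample_expression(10, s), 0.2 + 0.8 * exp(-1), tolerance = 1e-12)
  expect_equal(round(sample_expression(10, s), 4), 0.4943)
  s <- profile_spec("constant", value = 5)
  expect_equal(sample_expression(c(0, 3, 99), s), c(5, 5, 5))
  # logistic midpoint sits halfway between floor and ceiling
  s <- profile_spec("logistic_rise", midpoint = 16, steepness = 2,
                    floor = 0.1, ceiling = 0.9)
  expect_equal(profile_mean(s, 16), 0.5)
  # linear rise is floored
  s <- profile_spec("linear_rise", slope = 0.1, intercept = -1, floor = 0.05)
  expect_equal(profile_mean(s, c(0, 20)), c(0.05, 1))
})

test_that("profile validation rejects bad specifications", {
  expect_error(profile_spec("spline"), "unknown profile kind")
  expect_error(profile_spec("one_phase_decay", plateau = 0, y0 = 1, K = -1),
               "K must be >= 0")
  expect_error(profile_spec("logistic_rise", midpoint = 1, steepness = 1,
                            floor = 1, ceiling = 0), "ceiling")
  expect_error(profile_spec("constant", value = 1, cell_sd = -0.1), "cell_sd")
  expect_error(sample_expression(-1, profile_spec("constant", value = 1)),
               "ap_um")
})

test_that("cell noise is multiplicative lognormal with mean one", {
  s <- profile_spec("constant", value = 2, cell_sd = 0.3)
  set.seed(7)
  draws <- sample_expression(rep(0, 20000), s)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 2, tolerance = 0.02)
})

test_that("nucleus placement is seeded, separated, and counts clones exactly", {
  p <- phantom_params(n_cells = 50, clone_fraction = 0.2, seed = 42)
  a <- place_nuclei(p)
  b <- place_nuclei(p)
  expect_identical(a, b)
  expect_equal(sum(a$clone), 10)  # round(0.2 * 50)
  D <- as.matrix(dist(a[, c("z_um", "y_um", "x_um")]))
  diag(D) <- Inf
  expect_gte(min(D), 0.8 * 2.5)
  expect_true(all(a$ap_um >= 0))
})

test_that("patch mode places one contiguous clone of the requested size", {
  p <- tiny_params(seed = 3)
  p$clone_mode <- "patch"
  p$clone_fraction <- 0.25
  nuc <- place_nuclei(p)
  expect_equal(sum(nuc$clone), 3)
  # the patch is the seed cell plus its nearest neighbours: the largest
  # clone-to-clone gap is at most the patch diameter over the shell
  cl <- as.matrix(nuc[nuc$clone, c("z_um", "y_um", "x_um")])
  expect_lt(max(dist(cl)), max(dist(nuc[, c("z_um", "y_um", "x_um")])))
})

test_that("an overcrowded shell is refused", {
  p <- phantom_params(n_cells = 500,
                      shell = list(semi_axes = c(z = 1, y = 2, x = 2),
                                   thickness = 0.2))
  expect_error(place_nuclei(p), "shell too crowded")
})

test_that("phantom generation is bitwise deterministic for a fixed seed", {
  p <- tiny_params(seed = 11)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stack$data, b$stack$data)
})

test_that("rendered intensity is proportional to true expression", {
  # noise, blur and attenuation off: core means track truth almost exactly
  p <- clean_imaging(tiny_params(seed = 5))
  ph <- generate_phantom(p)
  tr <- ph$truth
  vol <- stack_channel(ph$stack, "eya")
  dims <- dim(vol); vs <- p$voxel_size
  meas <- vapply(seq_len(nrow(tr)), function(i) {
    vox <- germaquant:::sphere_voxels(dims, vs,
                                      c(tr$z_um[i], tr$y_um[i], tr$x_um[i]),
                                      tr$diameter_um[i] / 2)
    mean(vol[vox])
  }, numeric(1))
  fit <- summary(lm(meas ~ tr$eya_true))
  expect_gt(fit$r.squared, 0.999)
})

test_that("gradient realizability: decay K is recoverable from the truth table", {
  p <- tiny_params(seed = 9, n_cells = 40)
  p$marker_profiles$wnt_reporter$cell_sd <- 0
  tr <- generate_phantom(p, render = FALSE)$truth
  fit <- fit_one_phase_decay(tr$ap_um, tr$wnt_reporter_true)
  expect_equal(fit$K, 0.08, tolerance = 0.01)
})

test_that("depth attenuation follows the exponential closed form", {
  # two identical nuclei 20 um apart in depth, at the same voxel-grid phase
  # so their rendered blobs are congruent; residual attenuation 0.01/um
  truth <- data.frame(id = 1:2, z_um = c(2, 22), y_um = 3, x_um = 3,
                      ap_um = 0, diameter_um = 2.5, clone = FALSE,
                      nuclear_true = 1)
  p <- phantom_params(marker_profiles = list(nuclear = profile_spec("constant", value = 1)),
                      voxel_size = c(z = 0.4, y = 0.14, x = 0.14),
                      attenuation_per_um = 0.01, laser_corrected = FALSE,
                      psf_sigma = 0, background_level = 0,
                      noise = list(gaussian_sd = 0, poisson_scale = 0))
  st <- render_stack(truth, p)
  vol <- stack_channel(st, "nuclear")
  dims <- dim(vol); vs <- p$voxel_size
  m <- vapply(1:2, function(i) {
    vox <- germaquant:::sphere_voxels(dims, vs,
                                      c(truth$z_um[i], truth$y_um[i], truth$x_um[i]),
                                      1.25)
    mean(vol[vox])
  }, numeric(1))
  expect_equal(m[2] / m[1], exp(-0.2), tolerance = 0.02)
})

test_that("laser-corrected mode removes the depth bias entirely", {
  truth <- data.frame(id = 1:2, z_um = c(2, 22), y_um = 3, x_um = 3,
                      ap_um = 0, diameter_um = 2.5, clone = FALSE,
                      nuclear_true = 1)
  p <- phantom_params(marker_profiles = list(nuclear = profile_spec("constant", value = 1)),
                      voxel_size = c(z = 0.4, y = 0.14, x = 0.14),
                      attenuation_per_um = 0.01, laser_corrected = TRUE,
                      psf_sigma = 0, background_level = 0,
                      noise = list(gaussian_sd = 0, poisson_scale = 0))
  st <- render_stack(truth, p)
  vol <- stack_channel(st, "nuclear")
  dims <- dim(vol); vs <- p$voxel_size
  m <- vapply(1:2, function(i) {
    vox <- germaquant:::sphere_voxels(dims, vs,
                                      c(truth$z_um[i], truth$y_um[i], truth$x_um[i]),
                                      1.25)
    mean(vol[vox])
  }, numeric(1))
  expect_equal(m[2] / m[1], 1, tolerance = 0.02)
})

test_that("an oversized stack hits the voxel budget", {
  p <- tiny_params()
  p$max_voxels <- 1e4
  expect_error(generate_phantom(p), "voxel budget")
})

test_that("clone-marker polarity selects which nuclei carry the marker", {
  p <- clean_imaging(tiny_params(seed = 13))
  p$clone_fraction <- 0.5
  ph <- generate_phantom(p)
  vol <- stack_channel(ph$stack, "clone")
  dims <- dim(vol); vs <- p$voxel_size
  m <- vapply(seq_len(nrow(ph$truth)), function(i) {
    vox <- germaquant:::sphere_voxels(dims, vs,
      c(ph$truth$z_um[i], ph$truth$y_um[i], ph$truth$x_um[i]), 0.875)
    mean(vol[vox])
  }, numeric(1))
  # clone cores are bright; non-clone cores see at most faint neighbour bleed
  expect_gt(min(m[ph$truth$clone]), 5 * max(m[!ph$truth$clone]))
  expect_gt(min(m[ph$truth$clone]), 100)
  p$clone_polarity <- "negative"
  ph2 <- generate_phantom(p)
  vol2 <- stack_channel(ph2$stack, "clone")
  m2 <- vapply(seq_len(nrow(ph2$truth)), function(i) {
    vox <- germaquant:::sphere_voxels(dims, vs,
      c(ph2$truth$z_um[i], ph2$truth$y_um[i], ph2$truth$x_um[i]), 0.875)
    mean(vol2[vox])
  }, numeric(1))
  expect_gt(min(m2[!ph2$truth$clone]), 5 * max(m2[ph2$truth$clone]))
  expect_gt(min(m2[!ph2$truth$clone]), 100)
})
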