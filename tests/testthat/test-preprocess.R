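test_that("field-of-view crop matches the brute-force bounding box", {
  atlas <- test_atlas()
  vol <- atlas$template
  fov <- select_field_of_view(vol, air_threshold = -500, margin = 2L)
  # brute-force bounding box of above-threshold voxels (single component here)
  idx <- arrayInd(which(vol$data > -500), dim(vol$data))
  lo <- pmax(apply(idx, 2, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2, max) + 2L, dim(vol$data))
  expect_equal(unname(fov$crop_bounds["lo", ]), lo)
  expect_equal(unname(fov$crop_bounds["hi", ]), hi)
  # world coordinates of retained voxels unchanged
  expect_equal(voxel_to_world(fov$volume, c(0, 0, 0)),
               voxel_to_world(vol, lo - 1))
  # fully-foreground volume is a no-op crop
  flat <- ct_volume(array(100, c(10, 10, 10)), diag(4))
  fov2 <- select_field_of_view(flat)
  expect_equal(dim(fov2$volume$data), c(10, 10, 10))
  expect_error(select_field_of_view(ct_volume(array(-1000, c(8, 8, 8)),
                                              diag(4))),
               class = "nwuct_foreground_error")
})

test_that("Gaussian smoothing preserves constants, unit mass, and sigma 0", {
  set.seed(5)
  vol <- ct_volume(array(rnorm(10^3), c(10, 10, 10)), diag(4))
  expect_identical(ct_smooth(vol, 0)$data, vol$data)
  const <- ct_volume(array(7, c(10, 10, 10)), diag(4))
  expect_equal(ct_smooth(const, 2)$data, const$data)
  imp <- ct_volume(array(0, c(21, 21, 21)), diag(4))
  imp$data[11, 11, 11] <- 1
  expect_equal(sum(ct_smooth(imp, 1.5)$data), 1, tolerance = 1e-6)
  expect_error(ct_smooth(vol, -1), class = "nwuct_parameter_error")
})

test_that("skull stripping recovers the phantom brain without bone or scalp", {
  atlas <- test_atlas(plain = TRUE)
  vol <- atlas$template
  mask <- skull_strip(vol)
  truth <- atlas$brain_mask$data != 0
  dice <- 2 * sum(mask$data & truth) / (sum(mask$data) + sum(truth))
  expect_gte(dice, 0.99)
  expect_equal(sum(mask$data & (vol$data >= 300)), 0)

  # adding scalp soft tissue outside the shell leaves the mask unchanged
  dm <- dim(vol$data)
  ax <- lapply(1:3, function(i) {
    (seq_len(dm[i]) - 1 - (dm[i] - 1) / 2) * vol$spacing[i]
  })
  X <- array(ax[[1]], dm)
  Y <- array(rep(ax[[2]], each = dm[1]), dm)
  Z <- array(rep(ax[[3]], each = dm[1] * dm[2]), dm)
  rho2 <- (X / 60)^2 + (Y / 78)^2 + (Z / 55)^2
  scalp <- rho2 > 1.12^2 & rho2 <= 1.25^2
  with_scalp <- vol
  with_scalp$data[scalp] <- 40
  mask2 <- skull_strip(with_scalp)
  expect_identical(mask2$data, mask$data)

  expect_error(skull_strip(ct_volume(array(-1000, c(16, 16, 16)), diag(4))),
               class = "nwuct_extraction_error")
})

test_that("resampling is exact for identity and integer-voxel shifts", {
  atlas <- test_atlas()
  vol <- atlas$template
  expect_equal(resample_volume(vol, NULL, vol)$data, vol$data)
  # +1 voxel along x (one spacing unit): interior equals index-shift oracle
  tr <- make_transform(translation = c(vol$spacing[1], 0, 0))
  shifted <- resample_volume(vol, tr, vol)
  nx <- dim(vol$data)[1]
  expect_equal(shifted$data[1:(nx - 1), , ], vol$data[2:nx, , ])
  # nearest-neighbour label resampling introduces no new codes
  rl <- resample_volume(atlas$region_labels,
                        make_transform(rotation_deg = c(0, 0, 7),
                                       translation = c(3, -2, 1)),
                        atlas$template)
  expect_true(all(unique(as.vector(rl$data)) %in% 0:20))
})

test_that("transform constructors validate and compose correctly", {
  t1 <- make_transform(rotation_deg = c(0, 0, 30), translation = c(5, 0, 0))
  expect_equal(t1$dof_class, "rigid")
  comp <- compose_transforms(invert_transform(t1), t1)
  expect_equal(comp$matrix, diag(4), tolerance = 1e-12)
  expect_error(affine_transform(matrix(0, 4, 4)), class = "nwuct_affine_error")
  bad_rigid <- diag(4)
  bad_rigid[1, 1] <- 2
  expect_error(affine_transform(bad_rigid, "rigid"),
               class = "nwuct_affine_error")
})

test_that("self-registration returns the identity", {
  atlas <- test_atlas()
  reg <- register_to_atlas(atlas$template, atlas$brain_mask, atlas,
                           config = registration_config(dof_class = "rigid"))
  ident <- affine_transform(diag(4), "rigid")
  expect_lt(mean_displacement(reg$transform, ident, atlas), 0.1)
  expect_lt(max(abs(reg$transform$matrix[1:3, 4])), 0.1)
})

test_that("a known rigid perturbation is recovered below 1 mm", {
  atlas <- test_atlas()
  pose <- make_transform(rotation_deg = c(0, 0, 10), translation = c(8, -4, 3))
  ph <- generate_phantom(phantom_spec(pose = pose), atlas)
  mask <- skull_strip(ph$volume)
  reg <- register_to_atlas(ph$volume, mask, atlas,
                           config = registration_config(dof_class = "rigid"))
  expect_lt(mean_displacement(reg$transform, pose, atlas), 1)
})

test_that("anisotropic scaling is recovered within 2% per axis", {
  atlas <- test_atlas()
  pose <- make_transform(rotation_deg = c(0, 0, 5), translation = c(4, 2, -3),
                         scale = c(1.1, 0.95, 1.05))
  ph <- generate_phantom(phantom_spec(pose = pose), atlas)
  mask <- skull_strip(ph$volume)
  reg <- register_to_atlas(ph$volume, mask, atlas)
  sv_rec <- sort(svd(reg$transform$matrix[1:3, 1:3])$d)
  sv_true <- sort(svd(pose$matrix[1:3, 1:3])$d)
  expect_lt(max(abs(sv_rec / sv_true - 1)), 0.02)
  expect_lt(mean_displacement(reg$transform, pose, atlas), 1)

  # inverse consistency: registering the other way composes to identity
  fake_atlas <- structure(list(template = ph$volume, brain_mask = mask),
                          class = "region_atlas")
  reg_back <- register_to_atlas(atlas$template, atlas$brain_mask, fake_atlas)
  comp <- compose_transforms(reg$transform, reg_back$transform)
  expect_lt(mean_displacement(comp, affine_transform(diag(4)), atlas), 1)
})

test_that("registration refuses empty masks", {
  atlas <- test_atlas()
  empty <- atlas$brain_mask
  empty$data[] <- 0L
  expect_error(register_to_atlas(atlas$template, empty, atlas),
               class = "nwuct_mask_error")
})

test_that("the full preprocessing chain leaves in-pose densities unchanged", {
  atlas <- test_atlas()
  ph <- generate_phantom(phantom_spec(), atlas)   # atlas pose, no noise
  out <- nwu_pipeline(ph$volume, atlas)
  bm <- atlas$brain_mask$data != 0
  ref <- ct_smooth(atlas$template)   # the chain's own smoothing is not drift
  expect_lt(mean(abs(out$volume_atlas$data[bm] - ref$data[bm])), 0.5)
  expect_true(out$report$converged)
  expect_gt(out$report$brain_voxel_count, 0)
})
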