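test_that("HU window filtering keeps exactly the closed 20-50 interval", {
  vol <- ct_volume(array(35, c(6, 6, 6)), diag(4))
  mask <- array(TRUE, c(6, 6, 6))
  expect_equal(sum(filter_hu_window(vol, mask)), 6^3)
  vol$data[] <- 10   # encephalomalacia surrogate: all excluded
  expect_equal(sum(filter_hu_window(vol, mask)), 0)
  vol$data[] <- c(19.999, 20, 50, 50.001, 35, 90)
  expect_equal(sum(filter_hu_window(vol, mask)), 6^3 / 6 * 3)
  expect_error(filter_hu_window(vol, mask, c(50, 20)),
               class = "nwuct_parameter_error")
})

test_that("regional density equals hand arithmetic and flags empty regions", {
  toy <- toy_atlas()
  vol <- toy$template
  hus <- c(30, 35, 40, 25, 45, 50, 20, 33)
  vol$data[2:3, 4:5, 4:5] <- hus
  d <- region_density(vol, toy, "caudate", "left")
  expect_equal(d$mean_hu, mean(hus))   # = 34.75, hand-checkable
  expect_equal(d$valid_voxels, 8L)
  expect_equal(d$total_voxels, 8L)
  # voxel-order invariance
  vol2 <- vol
  vol2$data[2:3, 4:5, 4:5] <- rev(hus)
  expect_equal(region_density(vol2, toy, "caudate", "left")$mean_hu,
               mean(hus))
  # everything outside the window -> undefined, not zero
  vol$data[2:3, 4:5, 4:5] <- 90
  expect_true(is.na(region_density(vol, toy, "caudate", "left")$mean_hu))
})

test_that("NWU follows (1 - D_i/D_c) * 100 and is zero under symmetry", {
  atlas <- test_atlas()
  sym <- compute_nwu(atlas$template, atlas, side = "left")
  expect_equal(sym$per_region$nwu, rep(0, 10))
  expect_equal(sym$average_nwu, 0)
  expect_equal(sym$weighted_average_nwu, 0)

  # forced densities 30.8 vs 35.0 -> exactly 12%
  plain <- test_atlas(plain = TRUE)
  vol <- plain$template
  labs <- plain$region_labels$data
  vol$data[labs == 4L] <- 30.8    # left insula
  vol$data[labs == 14L] <- 35.0   # right insula
  res <- compute_nwu(vol, plain, side = "left")
  expect_equal(res$per_region$nwu[4], 12.0, tolerance = 1e-9)

  # multiplicative lesion: exactly 100 w in that region, 0 elsewhere
  ph <- generate_phantom(
    phantom_spec(lesions = list(list(region = "M3", w = 0.15))), plain)
  r2 <- compute_nwu(ph$volume, plain, side = "auto")
  expect_equal(r2$per_region$nwu[7], 15.0, tolerance = 0.1)
  expect_lt(max(abs(r2$per_region$nwu[-7])), 0.1)
  expect_equal(r2$average_nwu, 1.5, tolerance = 0.05)
  expect_equal(r2$ipsilateral_side, "left")
})

test_that("NWU is invariant to a multiplicative HU calibration factor", {
  atlas <- test_atlas(plain = TRUE)
  ph <- generate_phantom(
    phantom_spec(lesions = list(list(region = "insula", w = 0.2))), atlas)
  base <- compute_nwu(ph$volume, atlas, side = "left")
  scaled <- ph$volume
  inwin <- scaled$data >= 20 & scaled$data <= 50
  a <- 1.2   # keeps 22-45 HU inside the window
  scaled$data[inwin] <- scaled$data[inwin] * a
  res <- compute_nwu(scaled, atlas, side = "left", window = c(20 * a, 50 * a))
  expect_equal(res$per_region$nwu, base$per_region$nwu, tolerance = 1e-9)
})

test_that("artifact blobs outside the window do not move regional densities", {
  atlas <- test_atlas(plain = TRUE)
  clean <- generate_phantom(phantom_spec(), atlas)
  for (type in c("calcification", "hemorrhage", "encephalomalacia")) {
    art <- generate_phantom(
      phantom_spec(artifacts = list(list(type = type, region = "M5",
                                         side = "left"))), atlas)
    d_clean <- region_density(clean$volume, atlas, "M5", "left")
    d_art <- region_density(art$volume, atlas, "M5", "left")
    expect_identical(d_art$mean_hu, d_clean$mean_hu)
    expect_lt(d_art$valid_voxels, d_clean$valid_voxels)
  }
})

test_that("averaging rules match their definitions", {
  # equal volumes: weighted equals conventional
  v <- rep(c(10, 20), 5)
  agg <- aggregate_nwu(v, rep(100, 10))
  expect_equal(agg$average, agg$weighted_average)
  # one region at 20, nine at zero
  agg2 <- aggregate_nwu(c(20, rep(0, 9)), rep(100, 10))
  expect_equal(agg2$average, 2.0)
  # single defined region: both averages equal it
  agg3 <- aggregate_nwu(c(NA, 7.5, rep(NA, 8)), rep(100, 10))
  expect_equal(agg3$average, 7.5)
  expect_equal(agg3$weighted_average, 7.5)
  # unequal weights
  agg4 <- aggregate_nwu(c(10, 20), c(1, 3))
  expect_equal(agg4$weighted_average, 17.5)
  expect_error(aggregate_nwu(c(NA_real_, NA_real_), c(1, 1)),
               class = "nwuct_computation_error")
})

test_that("auto side selection finds the lesioned hemisphere", {
  atlas <- test_atlas()
  hits <- 0L
  n_rep <- 12L
  for (i in seq_len(n_rep)) {
    side <- if (i %% 2 == 0) "left" else "right"
    lesions <- lapply(c("M1", "M2", "M3", "insula", "caudate"),
                      function(r) list(region = r, w = 0.10))
    ph <- generate_phantom(phantom_spec(lesions = lesions, side = side,
                                        noise_sd = 2, seed = 100L + i), atlas)
    res <- compute_nwu(ph$volume, atlas, side = "auto")
    hits <- hits + (res$ipsilateral_side == side)
  }
  expect_equal(hits, n_rep)
})

test_that("average NWU grows linearly with lesion extent", {
  atlas <- test_atlas(plain = TRUE)
  w <- 0.2
  regions <- c("M1", "M2", "M4", "M5", "insula", "caudate")
  avgs <- vapply(seq_along(regions), function(k) {
    lesions <- lapply(regions[seq_len(k)], function(r) list(region = r, w = w))
    ph <- generate_phantom(phantom_spec(lesions = lesions), atlas)
    compute_nwu(ph$volume, atlas, side = "left")$average_nwu
  }, 0)
  expect_equal(avgs, seq_along(regions) * w * 100 / 10, tolerance = 0.02)
  expect_true(all(diff(avgs) > 0))
})

test_that("undefined regions are excluded, and all-undefined errors", {
  plain <- test_atlas(plain = TRUE)
  vol <- plain$template
  labs <- plain$region_labels$data
  vol$data[labs == 1L | labs == 11L] <- 90   # both caudates calcified out
  res <- compute_nwu(vol, plain, side = "left")
  expect_equal(res$regions_excluded, "caudate")
  expect_equal(sum(!is.na(res$per_region$nwu)), 9L)
  air <- ct_volume(array(-1000, dim(vol$data)), vol$affine)
  expect_error(compute_nwu(air, plain, side = "left"),
               class = "nwuct_computation_error")
})

test_that("tidy and glance expose the documented NWU tables", {
  atlas <- test_atlas()
  res <- compute_nwu(atlas$template, atlas, side = "left")
  td <- tidy(res)
  expect_equal(nrow(td), 10)
  expect_named(td, c("region", "nwu", "density_ipsi", "density_contra",
                     "valid_ipsi", "valid_contra", "weight_mm3"))
  gl <- glance(res)
  expect_equal(gl$n_regions_defined, 10L)
  expect_s3_class(autoplot(res), "ggplot")
})
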