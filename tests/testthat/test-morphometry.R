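test_that("volume is voxel count times voxel volume and additive", {
  v <- array(FALSE, c(10, 10, 10)); v[seq_len(1000)] <- TRUE
  expect_equal(compute_volume(binary_mask(v, 0.004)), 1000 * 0.004^3)
  expect_equal(compute_volume(binary_mask(array(FALSE, c(4, 4, 4)), 1)), 0)

  a <- ball_mask(3, n = 20, centre = c(5, 10, 10))
  b <- ball_mask(3, n = 20, centre = c(14, 10, 10))
  u <- binary_mask(a$voxels | b$voxels, 1)
  expect_equal(compute_volume(u), compute_volume(a) + compute_volume(b))
})

test_that("crofton_area equals the brute-force intercept oracle exactly", {
  expect_equal(crofton_area(binary_mask(array(FALSE, c(5, 5, 5)), 1)), 0)

  set.seed(7)
  for (i in 1:10) {
    dims <- sample(8:40, 3, replace = TRUE)
    m <- random_mask(dims, vs = stats::runif(1, 0.001, 2))
    expect_equal(crofton_area(m), oracle_crofton3(m))
  }
  # solid cuboid: oracle equivalence and sanity against the face count
  cub <- array(FALSE, c(20, 20, 20)); cub[5:15, 4:12, 3:17] <- TRUE
  cm <- binary_mask(cub, 0.5)
  expect_equal(crofton_area(cm), oracle_crofton3(cm))
})

test_that("crofton sphere estimate converges towards 4*pi*r^2", {
  errs <- vapply(c(8, 20, 32), function(r) {
    abs(crofton_area(ball_mask(r)) - 4 * pi * r^2) / (4 * pi * r^2)
  }, 0)
  expect_lte(errs[2], 0.05)
  expect_lt(errs[3], errs[1])
  # 13-direction mode agrees with the analytic sphere as well
  expect_equal(crofton_area(ball_mask(20), directions = 13), 4 * pi * 400,
               tolerance = 0.05)
})

test_that("orientation angle recovers known ellipsoid rotations", {
  o0 <- orientation_angle(ellipsoid_mask(0), u = c(0, 0, 1))
  expect_equal(o0$angle_deg, 0, tolerance = 1e-6)
  expect_true(all(diff(o0$eigenvalues) <= 0))

  o90 <- orientation_angle(ellipsoid_mask(90), u = c(0, 0, 1))
  expect_equal(o90$angle_deg, 90, tolerance = 1e-6)

  o30 <- orientation_angle(ellipsoid_mask(30), u = c(0, 0, 1))
  expect_equal(o30$angle_deg, 30, tolerance = 2 / 30)

  # scaling the grid leaves the angle unchanged
  m <- ellipsoid_mask(30)
  m2 <- binary_mask(m$voxels, 0.004)
  expect_equal(orientation_angle(m2, c(0, 0, 1))$angle_deg, o30$angle_deg)

  # angle is always folded to [0, 90]
  o150 <- orientation_angle(ellipsoid_mask(150), u = c(0, 0, 1))
  expect_equal(o150$angle_deg, 30, tolerance = 2 / 30)

  line <- array(FALSE, c(10, 10, 10)); line[, 5, 5] <- TRUE
  expect_error(orientation_angle(binary_mask(line, 1)), "collinear")
})

test_that("proportion_in_ventricle implements the printed ratio", {
  expect_equal(proportion_in_ventricle(1, 3), 0.25)
  expect_equal(proportion_in_ventricle(0, 2), 0)
  expect_equal(proportion_in_ventricle(2, 0), 1)
  expect_error(proportion_in_ventricle(0, 0), "zero")
  expect_error(proportion_in_ventricle(-1, 1), ">= 0")
})

test_that("split_by_plane conserves volume exactly and respects geometry", {
  b <- ball_mask(8, n = 24)
  ctr <- colMeans(mask_to_pointcloud(b))
  halves <- split_by_plane(b, ctr, c(1, 0, 0))
  expect_equal(compute_volume(halves$rostral) + compute_volume(halves$caudal),
               compute_volume(b))
  # symmetric ball: 50/50 within one voxel layer of the plane
  layer <- sum(abs(mask_to_pointcloud(b)[, 1] - ctr[1]) < 0.5)
  expect_lte(abs(sum(halves$rostral$voxels) - sum(halves$caudal$voxels)), layer)

  outside <- split_by_plane(b, c(-100, 0, 0), c(1, 0, 0))
  expect_identical(outside$rostral$voxels, b$voxels)
  expect_equal(sum(outside$caudal$voxels), 0)

  set.seed(3)
  for (i in 1:5) {
    m <- random_mask(c(15, 15, 15))
    h <- split_by_plane(m, stats::runif(3, 0, 15), stats::rnorm(3))
    expect_equal(compute_volume(h$rostral) + compute_volume(h$caudal),
                 compute_volume(m))
  }
  expect_error(split_by_plane(b, ctr, c(0, 0, 0)), "nonzero")
})

test_that("lateral measures are symmetric on the phantom and monotone in branch length", {
  ph <- small_phantom()
  lm <- lateral_measures(ph$plexus_truth, ph$ventricle_truth)
  vs <- ph$image$voxel_size_mm
  expect_lte(abs(lm$left_length_mm - lm$right_length_mm), 2 * vs)
  expect_lte(abs(lm$left_angle_deg - lm$right_angle_deg), 5)
  expect_lte(lm$total_length_mm, lm$ventricle_length_mm)
  expect_lte(lm$central_length_mm, lm$total_length_mm)

  long <- generate_embryo_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                               stage = "E17.5",
                                               branch_length_frac = 0.8))
  short <- generate_embryo_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                                stage = "E17.5",
                                                branch_length_frac = 0.4))
  llong <- lateral_measures(long$plexus_truth, long$ventricle_truth)
  lshort <- lateral_measures(short$plexus_truth, short$ventricle_truth)
  expect_gt(llong$left_length_mm, lshort$left_length_mm)
  expect_gt(llong$right_length_mm, lshort$right_length_mm)

  # one empty side: zero length, flagged angle
  half <- binary_mask(ph$plexus_truth$voxels &
                        slice.index(ph$plexus_truth$voxels, 3) <= 32, vs)
  lh <- lateral_measures(half, ph$ventricle_truth,
                         midline_point = colMeans(mask_to_pointcloud(ph$ventricle_truth)))
  expect_true(is.nan(lh$right_angle_deg) || lh$right_length_mm > 0)
})

test_that("build_report yields a finite, deterministic criterion panel", {
  ph <- small_phantom()
  r1 <- build_report(ph$plexus_truth, ph$ventricle_truth, sample = "phantom")
  r2 <- build_report(ph$plexus_truth, ph$ventricle_truth, sample = "phantom")
  for (f in chopct:::report_fields()) {
    expect_true(is.finite(r1[[f]]), info = f)
    expect_identical(r1[[f]], r2[[f]], info = f)
  }
  expect_gte(r1$proportion, 0); expect_lte(r1$proportion, 1)
  expect_equal(r1$rostral_volume_mm3 + r1$caudal_volume_mm3, r1$volume_mm3)
  expect_gte(r1$total_length_mm, r1$central_length_mm)

  # failures degrade to NaN with a log entry instead of aborting
  tiny <- binary_mask(array(FALSE, dim(ph$plexus_truth$voxels)),
                      ph$plexus_truth$voxel_size_mm)
  tiny$voxels[1, 1, 1] <- TRUE
  rb <- build_report(tiny, ph$ventricle_truth)
  expect_true(is.nan(rb$outgrowth_angle_deg))
  expect_gt(length(attr(rb, "log")), 0)
})
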