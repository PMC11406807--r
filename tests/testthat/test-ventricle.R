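test_that("preprocess median-filters and crops as specified", {
  const <- volume_image(array(7, c(12, 12, 12)), 1)
  expect_identical(preprocess(const)$voxels, const$voxels)

  salted <- const
  salted$voxels[6, 6, 6] <- 1000
  expect_identical(preprocess(salted)$voxels, const$voxels)

  p <- segmentation_params(crop_box = rbind(c(0, 10), c(0, 10), c(0, 10)))
  expect_identical(dim(preprocess(const, p)$voxels), c(10L, 10L, 10L))

  bad <- segmentation_params(crop_box = rbind(c(0, 20), c(0, 10), c(0, 10)))
  expect_error(preprocess(const, bad), "outside")
  expect_error(preprocess(volume_image(array(0, c(2, 2, 2)), 1)), "fit")
})

test_that("low-intensity thresholding separates a bimodal image exactly", {
  v <- array(120, c(10, 10, 10))
  v[3:5, 3:5, 3:5] <- 40
  img <- volume_image(v, 1)
  m <- threshold_low(img)
  expect_identical(m$voxels, v == 40)

  expect_warning(em <- threshold_low(volume_image(array(1, c(5, 5, 5)), 1)),
                 "degenerate")
  expect_equal(sum(em$voxels), 0)

  ph <- small_phantom()
  low <- threshold_low(preprocess(ph$image))
  cover <- sum(low$voxels & ph$ventricle_truth$voxels) / sum(ph$ventricle_truth$voxels)
  expect_gte(cover, 0.95)
})

test_that("component separation severs one-voxel bridges and sorts by size", {
  d <- c(40, 20, 20)
  z <- slice.index(array(0L, d), 1) - 1
  y <- slice.index(array(0L, d), 2) - 1
  x <- slice.index(array(0L, d), 3) - 1
  ball1 <- (z - 10)^2 + (y - 10)^2 + (x - 10)^2 <= 36
  ball2 <- (z - 29)^2 + (y - 10)^2 + (x - 10)^2 <= 16
  bridge <- y == 10 & x == 10 & z > 10 & z < 29
  m <- binary_mask(ball1 | ball2 | bridge, 1)
  expect_length(attr(label_components(m, 26), "sizes"), 1)  # bridged: one blob
  comps <- separate_components(m, segmentation_params(separation_radius = 2))
  expect_length(comps, 2)
  expect_gte(sum(comps[[1]]$voxels), sum(comps[[2]]$voxels))

  single <- separate_components(ball_mask(5, n = 16), segmentation_params())
  expect_length(single, 1)
  expect_identical(single[[1]]$voxels,
                   mask_open(ball_mask(5, n = 16), 2)$voxels)
})

test_that("mask_to_pointcloud maps voxel indices to millimetres", {
  v <- array(FALSE, c(6, 6, 6))
  v[3, 4, 5] <- TRUE  # 0-based index (2, 3, 4)
  pc <- mask_to_pointcloud(binary_mask(v, 0.004))
  expect_equal(unname(pc[1, ]), c(0.008, 0.012, 0.016))

  m <- ball_mask(4, n = 12)
  expect_equal(nrow(mask_to_pointcloud(m)), sum(m$voxels))
  expect_error(mask_to_pointcloud(binary_mask(array(FALSE, c(3, 3, 3)), 1)), "empty")
})

test_that("hausdorff matches hand values and the brute-force oracle", {
  a <- matrix(c(0, 0, 0), 1)
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(a, matrix(c(3, 4, 0), 1)), 5.0)

  set.seed(101)
  for (i in 1:5) {
    p <- matrix(stats::rnorm(600), ncol = 3)
    q <- matrix(stats::rnorm(600), ncol = 3)
    expect_equal(hausdorff(p, q, exact = TRUE), oracle_hausdorff(p, q))
  }
  # symmetry and identity of indiscernibles
  p <- matrix(stats::rnorm(150), ncol = 3)
  q <- p + 0.5
  expect_equal(hausdorff(p, q), hausdorff(q, p))
  expect_equal(hausdorff(p, p), 0)
})

test_that("ICP recovers known rigid motions and handles subsampling", {
  # an asymmetric cloud: rotation recovery on a (near-)spherical cloud is
  # ill-posed, so use seeded random points
  set.seed(17)
  src <- matrix(stats::runif(900), ncol = 3)

  idt <- icp_register(src, src)
  expect_lt(norm(idt$rotation - diag(3), "F"), 1e-6)
  expect_lt(idt$rmse, 1e-9)

  R <- rotation_matrix(c(0, 0, 1), 10)  # 10 degrees about the lateral axis
  tr <- c(1, 0, 0)
  tgt <- sweep(src %*% t(R), 2, tr, `+`)
  fit <- icp_register(src, tgt)
  expect_lt(norm(fit$rotation - R, "F"), 1e-3)
  expect_lt(sqrt(sum((fit$translation - tr)^2)), 1e-3)

  # every 2nd point of a voxel cloud against the full cloud
  full <- unclass(mask_to_pointcloud(ball_mask(6, n = 20, vs = 0.1)))
  half <- full[seq(1, nrow(full), by = 2), ]
  fit2 <- icp_register(half, full)
  expect_lte(fit2$rmse, 0.1)  # <= voxel size
})

test_that("select_ventricle picks the true lumen over a decoy", {
  ph <- small_phantom()
  ref <- small_reference()
  sp <- segmentation_params()
  low <- threshold_low(preprocess(ph$image), sp)
  cands <- separate_components(low, sp)
  expect_gte(length(cands), 2)  # lumen plus the decoy component
  sel <- suppressWarnings(select_ventricle(cands, ref, sp))
  expect_gte(dice(sel, ph$ventricle_truth), 0.8)

  one <- suppressWarnings(select_ventricle(cands[1], ref, sp))
  expect_identical(one$voxels, cands[[1]]$voxels)

  # exact tie: duplicated candidate; the first (largest) wins, with a message
  expect_message(tie <- suppressWarnings(
    select_ventricle(list(cands[[1]], cands[[1]]), ref, sp)), "tie")
  expect_identical(attr(tie, "selected"), 1L)
})

test_that("active-contour refinement is stable and respects iteration zero", {
  # noiseless two-level fixture: dark ellipsoidal cavity in uniform tissue
  d <- c(48, 48, 48)
  z <- slice.index(array(0L, d), 1) - 24
  y <- slice.index(array(0L, d), 2) - 24
  x <- slice.index(array(0L, d), 3) - 24
  truth <- binary_mask((z / 9)^2 + (y / 13)^2 + (x / 17)^2 <= 1, 1)
  v <- array(120, d); v[truth$voxels] <- 40
  img <- volume_image(v, 1)
  sp <- segmentation_params()

  init <- mask_dilate(truth, 2)
  ref <- refine_active_contour(img, init, sp)
  expect_gte(dice(ref, truth), 0.95)

  stay <- refine_active_contour(img, truth, sp)
  expect_gte(dice(stay, truth), 0.95)

  # on the full (three-level) phantom the refined lumen still tracks truth
  ph <- clean_phantom()
  refined <- refine_active_contour(ph$image, mask_dilate(ph$ventricle_truth, 2), sp)
  expect_gte(dice(refined, ph$ventricle_truth), 0.85)

  frozen <- refine_active_contour(img, init, segmentation_params(ac_iterations = 0))
  expect_identical(frozen$voxels, init$voxels)

  expect_error(refine_active_contour(img,
                                     binary_mask(array(FALSE, d), 1), sp),
               "empty")
})
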