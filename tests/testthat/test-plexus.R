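test_that("local range is zero on constants and full height at step edges", {
  const <- volume_image(array(3, c(8, 8, 8)), 1)
  expect_true(all(local_range(const)$voxels == 0))

  v <- array(0, c(8, 8, 8)); v[, , 5:8] <- 100
  rng <- local_range(volume_image(v, 1), 3)
  expect_true(all(rng$voxels >= 0))
  expect_equal(max(rng$voxels), 100)
  expect_true(all(rng$voxels[, , c(4, 5)] == 100))  # voxels straddling the edge
  expect_true(all(rng$voxels[, , c(1, 2, 8)] == 0))
})

test_that("primary mask extracts the bright gap content and spares the lumen", {
  ph <- small_phantom()
  sp <- segmentation_params()
  pre <- preprocess(ph$image, sp)
  vent <- suppressWarnings(refine_active_contour(
    pre, select_ventricle(separate_components(threshold_low(pre, sp), sp),
                          small_reference(), sp), sp))
  prim <- primary_mask(pre, vent, plexus_params())
  expect_gte(dice(prim, ph$plexus_truth), 0.7)
  expect_equal(sum(prim$voxels & vent$voxels), 0)
  expect_equal(sum(prim$voxels & !mask_dilate(ph$plexus_truth, 2)$voxels), 0)

  # a filled solid has no closable gaps -> empty mask and a warning
  solid <- ball_mask(8, n = 32)
  img <- volume_image(array(100, c(32, 32, 32)), 1)
  expect_warning(em <- primary_mask(img, solid, plexus_params()), "no gaps|no plexus")
  expect_equal(sum(em$voxels), 0)
})

test_that("E13.5 segmentation extends the primary mask to the whole plexus", {
  ph <- clean_phantom()  # noiseless: easy regime
  sp <- segmentation_params()
  pp <- plexus_params()
  pre <- preprocess(ph$image, sp)
  vent <- suppressWarnings(refine_active_contour(
    pre, select_ventricle(separate_components(threshold_low(pre, sp), sp),
                          generate_reference_ventricle(ph$spec, rotation_deg = 5),
                          sp), sp))
  prim <- primary_mask(pre, vent, pp)
  fin <- segment_e13(pre, prim, pp, sp)
  expect_gte(dice(fin, ph$plexus_truth), 0.95)
  expect_gte(dice(fin, prim), 0.3)  # extension, not replacement
  expect_length(attr(label_components(fin, 26), "sizes"), 1)
})

test_that("merge_manual is a checked voxelwise union", {
  a <- ball_mask(4, n = 24, centre = c(6, 11, 11))
  b <- ball_mask(4, n = 24, centre = c(16, 11, 11))
  empty <- binary_mask(array(FALSE, c(24, 24, 24)), 1)

  expect_identical(merge_manual(a, empty)$voxels, a$voxels)
  expect_equal(attr(merge_manual(a, empty), "added_voxels"), 0)

  disj <- merge_manual(a, b)
  expect_equal(compute_volume(disj), compute_volume(a) + compute_volume(b))

  c <- ball_mask(4, n = 24, centre = c(8, 11, 11))  # overlaps a
  expect_lt(compute_volume(merge_manual(a, c)),
            compute_volume(a) + compute_volume(c))

  expect_error(merge_manual(a, ball_mask(3, n = 12)), "share")
})

test_that("run_pipeline respects the stage switch and logs every stage", {
  ph <- small_phantom()
  ref <- small_reference()
  run <- suppressWarnings(run_pipeline(ph$image, ref, "E15.5_17.5"))
  expect_identical(run$final$voxels, run$primary$voxels)  # stops after primary
  expect_identical(vapply(run$log, `[[`, "", "stage"),
                   c("preprocess", "threshold_low", "separate_components",
                     "select_ventricle", "refine_active_contour", "primary_mask"))

  run13 <- suppressWarnings(run_pipeline(ph$image, ref, "E13.5"))
  expect_gte(dice(run13$final, ph$plexus_truth), 0.8)
  expect_equal(vapply(run13$log, `[[`, "", "stage")[7], "segment_e13")

  branches <- ball_mask(3, n = 64, vs = ph$image$voxel_size_mm,
                        centre = c(10, 10, 10))
  runm <- suppressWarnings(run_pipeline(ph$image, ref, "E15.5_17.5",
                                        manual_branches = branches))
  expect_identical(runm$final$voxels, runm$primary$voxels | branches$voxels)

  # stage failures carry the stage name
  flat <- volume_image(array(1, dim(ph$image$voxels)), ph$image$voxel_size_mm)
  expect_error(suppressWarnings(run_pipeline(flat, ref, "E13.5")),
               "separate_components|threshold_low")
})

test_that("segmentation quality does not improve as noise rises", {
  # smaller grid than the acceptance run, same property
  dice_at <- vapply(c(0, 10, 20), function(ns) {
    spn <- phantom_spec(grid_shape = c(64, 64, 64), noise_sigma = ns)
    phn <- generate_embryo_phantom(spn)
    refn <- generate_reference_ventricle(spn, rotation_deg = 5,
                                         translation_vox = c(1, 1, 0))
    suppressWarnings(dice(run_pipeline(phn$image, refn, "E13.5")$final,
                          phn$plexus_truth))
  }, 0)
  expect_true(all(diff(dice_at) <= 0.02))
})
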