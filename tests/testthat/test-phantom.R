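test_that("phantom generation is deterministic under a fixed seed", {
  sp <- phantom_spec(grid_shape = c(48, 48, 48), noise_sigma = 8, seed = 1L)
  a <- generate_embryo_phantom(sp)
  b <- generate_embryo_phantom(sp)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$ventricle_truth$voxels, b$ventricle_truth$voxels)
  c <- generate_embryo_phantom(phantom_spec(grid_shape = c(48, 48, 48),
                                            noise_sigma = 8, seed = 2L))
  expect_false(identical(a$image$voxels, c$image$voxels))
})

test_that("noiseless phantom is built exactly from the stated levels", {
  sp <- phantom_spec(grid_shape = c(48, 48, 48), noise_sigma = 0,
                     plexus_level = 200, tissue_level = 120, ventricle_level = 40)
  ph <- generate_embryo_phantom(sp)
  expect_true(all(ph$image$voxels[ph$plexus_truth$voxels] == 200))
  expect_true(all(ph$image$voxels[ph$ventricle_truth$voxels] == 40))
  expect_true(all(ph$image$voxels[ph$tissue_truth$voxels] == 120))
})

test_that("ground-truth masks are disjoint and the plexus is one 26-connected component", {
  for (n in c(48, 96)) {
    ph <- generate_embryo_phantom(phantom_spec(grid_shape = rep(n, 3)))
    expect_equal(sum(ph$ventricle_truth$voxels & ph$plexus_truth$voxels), 0)
    expect_length(attr(label_components(ph$plexus_truth, 26), "sizes"), 1)
    expect_identical(dim(ph$plexus_truth$voxels), dim(ph$image$voxels))
  }
})

test_that("spec validation rejects impossible phantoms", {
  expect_error(phantom_spec(grid_shape = c(16, 64, 64)), "grid_shape")
  expect_error(phantom_spec(tissue_level = 300), "levels")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(branch_length_frac = 1.5), "branch_length_frac")
})

test_that("realized CNR on truth masks matches level difference over noise", {
  ph <- small_phantom()  # levels 200/120, sigma 10 -> CNR 8
  res <- contrast_to_noise(ph$image, ph$plexus_truth, ph$tissue_truth)
  expect_gt(sum(ph$tissue_truth$voxels), 1e4)
  expect_equal(res$ratio, 8.0, tolerance = 0.5 / 8.0)
})

test_that("reference ventricle honours the rigid jitter contract", {
  sp <- phantom_spec(grid_shape = c(48, 48, 48))
  truth <- generate_embryo_phantom(sp)$ventricle_truth
  ident <- generate_reference_ventricle(sp)
  expect_identical(ident$voxels, truth$voxels)

  rot <- generate_reference_ventricle(sp, rotation_deg = 5)
  expect_gt(hausdorff(mask_to_pointcloud(rot), mask_to_pointcloud(truth)), 0)

  tr <- generate_reference_ventricle(sp, translation_vox = c(10, 0, 0))
  ct <- colMeans(mask_to_pointcloud(truth))
  cr <- colMeans(mask_to_pointcloud(tr))
  expect_equal(unname(cr[1] - ct[1]), 10 * sp$voxel_size_mm, tolerance = 1e-6)
  expect_equal(unname(cr[2] - ct[2]), 0, tolerance = 1e-9)

  grown <- generate_reference_ventricle(sp, boundary = 1L)
  expect_gt(sum(grown$voxels), sum(truth$voxels))
})

test_that("landmark set generator obeys its shape and noise contracts", {
  sets <- generate_landmark_sets(5, k = 10, noise_sigma_mm = 0, seed = 11)
  expect_length(sets, 5)
  expect_true(all(vapply(sets, function(s) nrow(s$points), 0L) == 10L))
  # noiseless sets are exact similarity transforms of the base
  g <- generalized_procrustes(sets)
  expect_lt(max(g$distances), 1e-8)
  # reproducible under the same seed
  again <- generate_landmark_sets(5, k = 10, noise_sigma_mm = 0, seed = 11)
  expect_identical(sets[[3]]$points, again[[3]]$points)
  # k != 10 uses the helix base
  hx <- generate_landmark_sets(2, k = 6, noise_sigma_mm = 0.01, seed = 1)
  expect_equal(nrow(hx[[1]]$points), 6)
  expect_error(generate_landmark_sets(1, k = 2), "k must be")
})
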