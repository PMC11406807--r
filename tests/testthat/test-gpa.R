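fixed_tetra <- function() {
  list(x = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE),
       y = matrix(c(0.05, 0, 0, 1.1, 0, 0.1, 0, 0.9, -0.05, 0.2, 0, 1.2),
                  4, 3, byrow = TRUE))
}

test_that("pairwise Procrustes distance is zero for similarity-equivalent shapes", {
  x <- fixed_tetra()$x
  expect_equal(procrustes_pair(x, x)$distance, 0, tolerance = 1e-12)

  R <- rotation_matrix(c(1, 2, 3), 37)
  y <- sweep(2 * x %*% t(R), 2, c(0.3, -0.2, 5), `+`)
  expect_lt(procrustes_pair(x, y, allow_scale = TRUE)$distance, 1e-10)
  # without scale removal the size difference remains
  expect_gt(procrustes_pair(x, y, allow_scale = FALSE)$distance, 0.1)

  expect_error(procrustes_pair(x, matrix(0, 4, 3)), "coincide")
  expect_error(procrustes_pair(x, x[1:3, ]), "landmark count")
})

test_that("pairwise distance matches the independent SVD oracle", {
  tt <- fixed_tetra()
  expect_equal(procrustes_pair(tt$x, tt$y, allow_scale = TRUE)$distance,
               oracle_procrustes(tt$x, tt$y, allow_scale = TRUE),
               tolerance = 1e-12)
  expect_equal(procrustes_pair(tt$x, tt$y, allow_scale = FALSE)$distance,
               oracle_procrustes(tt$x, tt$y, allow_scale = FALSE),
               tolerance = 1e-12)
})

test_that("GPA removes translation, scale and rotation", {
  sets <- generate_landmark_sets(5, noise_sigma_mm = 0, seed = 5)
  g <- generalized_procrustes(sets)
  expect_true(g$converged)
  expect_lt(max(g$distances), 1e-8)
  # mean configuration is centred at the origin
  expect_lt(max(abs(colMeans(g$mean_config))), 1e-10)
})

test_that("GPA distances grow with landmark noise and ignore input order", {
  means <- vapply(c(0.01, 0.05), function(s) {
    mean(generalized_procrustes(
      generate_landmark_sets(8, noise_sigma_mm = s, seed = 21))$distances)
  }, 0)
  expect_lt(means[1], means[2])

  sets <- generate_landmark_sets(6, noise_sigma_mm = 0.02, seed = 9)
  g1 <- suppressWarnings(generalized_procrustes(sets, tol = 1e-10))
  perm <- c(4, 1, 6, 2, 5, 3)
  g2 <- suppressWarnings(generalized_procrustes(sets[perm], tol = 1e-10))
  expect_equal(g2$distances, g1$distances[perm], tolerance = 1e-6)
})

test_that("distances are invariant under a common similarity transform", {
  sets <- generate_landmark_sets(5, noise_sigma_mm = 0.03, seed = 13)
  base <- suppressWarnings(generalized_procrustes(sets, tol = 1e-10))
  R <- rotation_matrix(c(0, 1, 1), 25)
  moved <- lapply(sets, function(s) {
    landmark_config(sweep(1.7 * s$points %*% t(R), 2, c(1, -2, 0.5), `+`),
                    label = s$label)
  })
  g <- suppressWarnings(generalized_procrustes(moved, tol = 1e-10))
  expect_equal(g$distances, base$distances, tolerance = 1e-8)
})

test_that("reference-mean mode reproduces the iterative result and allows n = 1", {
  sets <- generate_landmark_sets(5, noise_sigma_mm = 0.02, seed = 2)
  g <- suppressWarnings(generalized_procrustes(sets, tol = 1e-10))
  ref <- landmark_config(g$mean_config, label = "mean")
  gr <- gpa_against_reference(sets, ref)
  expect_equal(gr$distances, g$distances, tolerance = 1e-8)
  expect_equal(gr$iterations, 1L)

  solo <- gpa_against_reference(list(ref), ref)
  expect_lt(solo$distances, 1e-12)
})

test_that("landmark subsets preserve order and reject bad indices", {
  cfg <- generate_landmark_sets(1, seed = 4)[[1]]
  expect_identical(subset_landmarks(cfg, 1:10)$points, cfg$points)
  sub <- subset_landmarks(cfg, c(5, 6, 7, 8, 10))
  expect_equal(nrow(sub$points), 5)
  expect_identical(unname(sub$points[1, ]), unname(cfg$points[5, ]))
  expect_error(subset_landmarks(cfg, c(5, 5, 6)), "duplicate")
  expect_error(subset_landmarks(cfg, c(9, 10, 11)), "out of range")
  expect_error(subset_landmarks(cfg, c(1, 2)), "at least 3")
})
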