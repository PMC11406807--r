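make_cnr_fixture <- function() {
  # fg voxels all 100; bg voxels alternating 40/60: mean 50, population sd 10
  v <- array(0, c(4, 5, 5))
  fg <- array(FALSE, dim(v)); bg <- array(FALSE, dim(v))
  fg[1:2, , ] <- TRUE
  bg[3:4, , ] <- TRUE
  v[fg] <- 100
  v[bg] <- rep(c(40, 60), length.out = sum(bg))
  list(img = volume_image(v, 1), fg = binary_mask(fg, 1), bg = binary_mask(bg, 1))
}

test_that("contrast-to-noise implements |mean_fg - mean_bg| / sd_bg", {
  fx <- make_cnr_fixture()
  res <- contrast_to_noise(fx$img, fx$fg, fx$bg)
  expect_equal(res$mean_fg, 100)
  expect_equal(res$mean_bg, 50)
  expect_equal(res$sigma_bg, 10)
  expect_equal(res$ratio, 5.0)
  expect_equal(res$decibels, 20 * log10(5))
  expect_equal(res$decibels10, 10 * log10(5))

  # fg == bg region -> ratio 0
  same <- contrast_to_noise(fx$img, fx$bg, fx$bg)
  expect_equal(same$ratio, 0)
})

test_that("CNR is invariant to intensity scaling and shifts", {
  fx <- make_cnr_fixture()
  base <- contrast_to_noise(fx$img, fx$fg, fx$bg)$ratio
  for (c in c(0.5, 3)) {
    scaled <- volume_image(fx$img$voxels * c, 1)
    expect_equal(contrast_to_noise(scaled, fx$fg, fx$bg)$ratio, base)
    shifted <- volume_image(fx$img$voxels + 17, 1)
    expect_equal(contrast_to_noise(shifted, fx$fg, fx$bg)$ratio, base)
  }
})

test_that("degenerate background and empty masks are handled", {
  v <- volume_image(array(c(1, 2), c(2, 2, 2)), 1)
  fg <- binary_mask(array(c(TRUE, FALSE), c(2, 2, 2)), 1)
  bg <- binary_mask(array(c(FALSE, TRUE), c(2, 2, 2)), 1)
  flat <- volume_image(array(0, c(2, 2, 2)), 1)
  flat$voxels[fg$voxels] <- 5
  res <- contrast_to_noise(flat, fg, bg)  # sigma_bg = 0, means differ
  expect_true(is.infinite(res$ratio))
  expect_true(res$flag_infinite)
  empty <- binary_mask(array(FALSE, c(2, 2, 2)), 1)
  expect_error(contrast_to_noise(v, empty, bg), "nonempty")
})
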