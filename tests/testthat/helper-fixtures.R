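# Shared fixtures and independent oracles. Phantoms used by several files are
# cached per test run so generation cost is paid once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small default-contrast phantom for unit tests (64^3, noise sigma 10)
small_phantom <- function() {
  cached("small_phantom",
         generate_embryo_phantom(phantom_spec(grid_shape = c(64, 64, 64))))
}

small_reference <- function() {
  cached("small_reference",
         generate_reference_ventricle(phantom_spec(grid_shape = c(64, 64, 64)),
                                      rotation_deg = 5,
                                      translation_vox = c(1, 1, 0)))
}

# noiseless phantom for active-contour / easy-regime checks (96^3)
clean_phantom <- function() {
  cached("clean_phantom",
         generate_embryo_phantom(phantom_spec(grid_shape = c(96, 96, 96),
                                              noise_sigma = 0)))
}

# digitized ball mask, voxel size vs
ball_mask <- function(r, n = 2 * r + 5, vs = 1, centre = rep((n - 1) / 2, 3)) {
  z <- slice.index(array(0L, c(n, n, n)), 1) - 1
  y <- slice.index(array(0L, c(n, n, n)), 2) - 1
  x <- slice.index(array(0L, c(n, n, n)), 3) - 1
  binary_mask((z - centre[1])^2 + (y - centre[2])^2 + (x - centre[3])^2 <= r^2, vs)
}

# digitized prolate ellipsoid (long semi-axis a along x), rotated by theta
# degrees in the x-z plane, axis ratio a/b
ellipsoid_mask <- function(theta_deg, a = 45, b = 15, n = 2 * a + 20, vs = 1) {
  c0 <- (n - 1) / 2
  z <- slice.index(array(0L, c(n, n, n)), 1) - 1 - c0
  y <- slice.index(array(0L, c(n, n, n)), 2) - 1 - c0
  x <- slice.index(array(0L, c(n, n, n)), 3) - 1 - c0
  th <- theta_deg * pi / 180
  xr <- cos(th) * x + sin(th) * z
  zr <- -sin(th) * x + cos(th) * z
  binary_mask((xr / a)^2 + (y / b)^2 + (zr / b)^2 <= 1, vs)
}

# O(N^2) brute-force Hausdorff oracle (double loop via outer distances)
oracle_hausdorff <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# brute-force Crofton oracle: per-line run counting with rle along each of
# the three grid axes
oracle_crofton3 <- function(mask) {
  m <- mask$voxels
  vs <- mask$voxel_size_mm
  d <- dim(m)
  runs_line <- function(v) {
    r <- rle(v)
    sum(r$values)
  }
  chi <- 0
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) chi <- chi + runs_line(m[, j, k])
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) chi <- chi + runs_line(m[i, , k])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) chi <- chi + runs_line(m[i, j, ])
  4 * chi * vs^2 / 3
}

# random blobby mask: thresholded, lightly smoothed white noise
random_mask <- function(dims, vs = 1, frac = 0.4) {
  raw <- array(stats::rnorm(prod(dims)), dims)
  sm <- raw
  for (ax in 1:3) {
    idx <- pmin(pmax(seq_len(dims[ax]) + 1L, 1L), dims[ax])
    sm <- sm + switch(ax, raw[idx, , , drop = FALSE], raw[, idx, , drop = FALSE],
                      raw[, , idx, drop = FALSE])
  }
  binary_mask(sm > stats::quantile(sm, 1 - frac), vs)
}

# independent SVD-based pairwise Procrustes oracle (kept deliberately
# separate from the package implementation)
oracle_procrustes <- function(x, y, allow_scale = TRUE) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(t(yc) %*% xc)
  rot <- s$u %*% diag(c(1, 1, det(s$u %*% t(s$v)))) %*% t(s$v)
  yr <- yc %*% rot
  sc <- if (allow_scale) sum(xc * yr) / sum(yr^2) else 1
  sum((xc - sc * yr)^2)
}

mesh_euler_characteristic <- function(mesh) {
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  ne <- nrow(unique(edges))
  nrow(mesh$vertices) - ne + nrow(mesh$faces)
}
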