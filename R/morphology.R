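#' Integer offsets of a digital ball structuring element
#'
#' All integer offsets `(dz, dy, dx)` with squared Euclidean norm
#' `<= radius^2`. Radius 1 gives the 6-neighbourhood plus centre.
#'
#' @param radius non-negative integer voxel radius.
#' @return n x 3 integer matrix.
#' @keywords internal
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  if (r < 0L) stop("radius must be >= 0")
  s <- -r:r
  g <- expand.grid(dz = s, dy = s, dx = s)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  m <- as.matrix(g)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

mask_apply_cpp <- function(mask, fun, offsets) {
  v <- fun(as.logical(mask$voxels), dim(mask$voxels), offsets)
  binary_mask(array(v, dim(mask$voxels)), mask$voxel_size_mm)
}

#' Morphological dilation/erosion/opening/closing with a ball element
#'
#' Standard binary morphology on the voxel grid. Outside the grid counts as
#' background, so erosion (and hence opening/closing) shrinks objects touching
#' the image border.
#'
#' @param mask a `binary_mask`.
#' @param radius ball radius in voxels.
#' @return A `binary_mask` of the same geometry.
#' @export
mask_dilate <- function(mask, radius) {
  mask_apply_cpp(mask, cpp_dilate, ball_offsets(radius))
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, radius) {
  mask_apply_cpp(mask, cpp_erode, ball_offsets(radius))
}

#' @rdname mask_dilate
#' @export
mask_open <- function(mask, radius) {
  off <- ball_offsets(radius)
  mask_apply_cpp(mask_apply_cpp(mask, cpp_erode, off), cpp_dilate, off)
}

#' @rdname mask_dilate
#' @export
mask_close <- function(mask, radius) {
  off <- ball_offsets(radius)
  mask_apply_cpp(mask_apply_cpp(mask, cpp_dilate, off), cpp_erode, off)
}

#' Label connected components of a mask
#'
#' @param mask a `binary_mask`.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of component labels (0 = background), with an
#'   attribute `sizes` giving voxel counts per label.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  lab <- cpp_label_components(as.logical(mask$voxels), dim(mask$voxels),
                              as.integer(connectivity))
  lab <- array(lab, dim(mask$voxels))
  n <- max(lab)
  sizes <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  attr(lab, "sizes") <- sizes
  lab
}

#' Otsu's threshold of a numeric sample
#'
#' Maximizes between-class variance on a fixed-bin histogram. Returns the bin
#' upper edge separating the two classes; values `< threshold` fall in the
#' lower class.
#'
#' @param x numeric vector of intensities.
#' @param nbins histogram bin count.
#' @return Scalar threshold; `NA` if `x` is (near-)constant.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}
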