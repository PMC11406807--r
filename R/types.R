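#' 3D grayscale volume with physical voxel size
#'
#' The in-memory currency for micro-CT stacks: a 3D numeric array indexed
#' `(z, y, x)` (z = rostrocaudal stack axis) together with the isotropic edge
#' length of one voxel in millimetres. Physical coordinate of voxel
#' `(i, j, k)` (0-based) is `c(i, j, k) * voxel_size_mm`.
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param voxel_size_mm isotropic voxel edge length in mm (> 0).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size_mm) {
  voxels <- as_array3(voxels)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0) {
    stop("voxel_size_mm must be a single positive finite number")
  }
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels))) stop("volume intensities must all be finite")
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm),
            class = "volume_image")
}

#' 3D binary mask sharing a volume's geometry
#'
#' @param voxels 3D logical (or coercible) array; `TRUE` = foreground.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, voxel_size_mm) {
  voxels <- as_array3(voxels)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0) {
    stop("voxel_size_mm must be a single positive finite number")
  }
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm),
            class = "binary_mask")
}

as_array3 <- function(x) {
  if (is.null(dim(x))) stop("voxels must be a 3D array")
  if (length(dim(x)) != 3L) stop("voxels must have exactly 3 dimensions")
  if (any(dim(x) < 1L)) stop("all three dimensions must be >= 1")
  x
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels, %.4g mm/voxel, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %.4g mm/voxel, %d foreground\n",
              d[1], d[2], d[3], x$voxel_size_mm, sum(x$voxels)))
  invisible(x)
}

#' Ordered, labelled 3D landmark configuration
#'
#' Landmark order encodes anatomical correspondence across samples, so it is
#' preserved by every operation in the package.
#'
#' @param points K x 3 numeric matrix of coordinates in mm (K >= 3).
#' @param label optional sample identifier.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, label = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("landmarks must be a K x 3 matrix")
  if (nrow(points) < 3L) stop("at least 3 landmarks are required")
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, label = as.character(label)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> '%s', %d landmarks (mm)\n",
              x$label, nrow(x$points)))
  invisible(x)
}

stopifnot_same_geometry <- function(a, b, what = "inputs") {
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      abs(a$voxel_size_mm - b$voxel_size_mm) > 1e-12) {
    stop(what, " must share grid shape and voxel size")
  }
  invisible(TRUE)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_same_geometry(a, b, "dice masks")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}
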