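#' Segmentation parameter block
#'
#' Parameters steering 4th-ventricle localization. Defaults are the smallest
#' effective choices at the scale of the bundled phantom; all are exposed here
#' and in the JSON run configuration.
#'
#' @param median_window odd 3D median-filter window (voxels per axis).
#' @param crop_box optional 3 x 2 integer matrix of 0-based `[start, end)`
#'   index bounds per axis `(z, y, x)`; `NULL` disables cropping.
#' @param threshold_method `"otsu"` (default) or `"percentile"`.
#' @param threshold_percentile percentile in (0, 100) for the percentile
#'   method: voxels below this intensity percentile are kept.
#' @param separation_radius ball radius (voxels) of the morphological opening
#'   that severs false connections before connected components.
#' @param connectivity 6 or 26 (foreground connectivity).
#' @param icp_max_iter,icp_tol iterative-closest-point iteration cap and
#'   relative RMSE convergence tolerance.
#' @param ac_iterations,ac_smoothing active-contour sweeps and per-sweep
#'   binary-median smoothing passes.
#' @param max_points point-cloud subsampling cap for ICP/Hausdorff (seeded).
#' @param stage developmental stage switch, `"E13.5"` or `"E15.5_17.5"`.
#' @param seed seed for the point-cloud subsampler.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(median_window = 3L, crop_box = NULL,
                                threshold_method = c("otsu", "percentile"),
                                threshold_percentile = 5,
                                separation_radius = 2L, connectivity = 26L,
                                icp_max_iter = 50L, icp_tol = 1e-5,
                                ac_iterations = 30L, ac_smoothing = 1L,
                                max_points = 5000L,
                                stage = c("E13.5", "E15.5_17.5"),
                                seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  stage <- match.arg(stage)
  if (median_window %% 2L != 1L || median_window < 1L) {
    stop("median_window must be odd and >= 1")
  }
  if (threshold_percentile <= 0 || threshold_percentile >= 100) {
    stop("threshold_percentile must lie in (0, 100)")
  }
  if (icp_max_iter < 1L || ac_iterations < 0L) stop("iteration counts must be >= 1 (>= 0 for ac)")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(median_window = as.integer(median_window), crop_box = crop_box,
                 threshold_method = threshold_method,
                 threshold_percentile = threshold_percentile,
                 separation_radius = as.integer(separation_radius),
                 connectivity = as.integer(connectivity),
                 icp_max_iter = as.integer(icp_max_iter), icp_tol = icp_tol,
                 ac_iterations = as.integer(ac_iterations),
                 ac_smoothing = as.integer(ac_smoothing),
                 max_points = as.integer(max_points), stage = stage,
                 seed = as.integer(seed)),
            class = "segmentation_params")
}

#' Preprocess a volume: 3D median filter, then crop
#'
#' @param image a [volume_image].
#' @param p a [segmentation_params()].
#' @return A [volume_image] (voxel size unchanged).
#' @export
preprocess <- function(image, p = segmentation_params()) {
  d <- dim(image$voxels)
  if (any(p$median_window > d)) stop("median window does not fit within the image")
  v <- image$voxels
  if (p$median_window > 1L) {
    v <- array(cpp_median_filter3(as.vector(v), d, p$median_window), d)
  }
  if (!is.null(p$crop_box)) {
    cb <- p$crop_box
    if (!is.matrix(cb) || !all(dim(cb) == c(3L, 2L))) {
      stop("crop_box must be a 3 x 2 matrix of 0-based [start, end) bounds")
    }
    if (any(cb[, 1] < 0) || any(cb[, 2] > d) || any(cb[, 2] <= cb[, 1])) {
      stop("crop_box lies outside the image")
    }
    v <- v[(cb[1, 1] + 1):cb[1, 2], (cb[2, 1] + 1):cb[2, 2],
           (cb[3, 1] + 1):cb[3, 2], drop = FALSE]
  }
  volume_image(v, image$voxel_size_mm)
}

#' Extract low-intensity voxels (CSF-filled ventricular system)
#'
#' Thresholds the intensity histogram (Otsu by default) and keeps voxels
#' *below* the threshold -- the ventricular system appears dark in
#' contrast-enhanced micro-CT because it is filled with CSF.
#'
#' @inheritParams preprocess
#' @return A [binary_mask]; empty (with a warning) for a constant image.
#' @export
threshold_low <- function(image, p = segmentation_params()) {
  x <- as.vector(image$voxels)
  thr <- if (p$threshold_method == "otsu") {
    otsu_threshold(x)
  } else {
    as.numeric(stats::quantile(x, p$threshold_percentile / 100))
  }
  if (is.na(thr)) {
    warning("degenerate (constant) image: returning empty mask")
    return(binary_mask(array(FALSE, dim(image$voxels)), image$voxel_size_mm))
  }
  m <- binary_mask(image$voxels < thr, image$voxel_size_mm)
  attr(m, "threshold") <- thr
  m
}

#' Split a mask into connected components after a separating opening
#'
#' Morphological opening with a ball of `separation_radius` severs thin false
#' connections (e.g. between the 4th ventricle and the rest of the ventricular
#' system); the surviving foreground is then labelled and returned as one mask
#' per component, largest first.
#'
#' @param mask a nonempty [binary_mask].
#' @param p a [segmentation_params()].
#' @return List of [binary_mask]s sorted by voxel count (descending); empty
#'   list with a warning if the opening removes everything.
#' @export
separate_components <- function(mask, p = segmentation_params()) {
  if (sum(mask$voxels) == 0L) stop("mask is empty")
  opened <- if (p$separation_radius > 0L) mask_open(mask, p$separation_radius) else mask
  if (sum(opened$voxels) == 0L) {
    warning("opening removed all foreground voxels")
    return(list())
  }
  lab <- label_components(opened, p$connectivity)
  sizes <- attr(lab, "sizes")
  ord <- order(sizes, decreasing = TRUE)
  lapply(ord, function(l) {
    binary_mask(lab == l, mask$voxel_size_mm)
  })
}

#' Convert a mask to a physical-coordinate point cloud
#'
#' One point per foreground voxel centre, `index * voxel_size_mm` (0-based
#' indices, coordinate order `(z, y, x)`).
#'
#' @param mask a nonempty [binary_mask].
#' @param max_points optional cap; larger clouds are subsampled without
#'   replacement (seeded, reproducible).
#' @param seed subsampling seed.
#' @return n x 3 numeric matrix of class `point_cloud` (mm).
#' @export
mask_to_pointcloud <- function(mask, max_points = NULL, seed = 1L) {
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("mask is empty")
  if (!is.null(max_points) && length(idx) > max_points) {
    idx <- with_seed(seed, sort(sample(idx, max_points)))
  }
  pts <- index_to_coords(idx, dim(mask$voxels)) * mask$voxel_size_mm
  structure(pts, class = c("point_cloud", class(pts)))
}

#' Symmetric Hausdorff distance between point clouds, in mm
#'
#' `max(sup_a inf_b d, sup_b inf_a d)` with the Euclidean metric. Clouds
#' larger than `max_points` are subsampled (seeded) unless `exact = TRUE`;
#' the exact mode is O(N^2).
#'
#' @param a,b point matrices (n x 3, mm).
#' @param max_points subsampling cap.
#' @param exact disable subsampling.
#' @param seed subsampling seed.
#' @return Scalar distance in mm.
#' @export
hausdorff <- function(a, b, max_points = 5000L, exact = FALSE, seed = 1L) {
  a <- unclass(a); b <- unclass(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("point clouds must be nonempty")
  if (!exact) {
    if (nrow(a) > max_points) a <- with_seed(seed, a[sort(sample(nrow(a), max_points)), , drop = FALSE])
    if (nrow(b) > max_points) b <- with_seed(seed + 1L, b[sort(sample(nrow(b), max_points)), , drop = FALSE])
  }
  cpp_hausdorff(a, b)
}

# Kabsch: least-squares rigid fit mapping x onto y (rows are points).
# Returns R (3x3, det +1) and t such that x %*% t(R) + t approximates y.
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  M <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))  # t(x_c) %*% y_c
  s <- svd(M)
  W <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  # rows transform: x_c %*% (u W v^T) aligns to y_c; as an operator R p with
  # column vectors this is R = v W^T u^T
  Rop <- s$v %*% W %*% t(s$u)
  list(rotation = Rop, translation = as.numeric(cy - Rop %*% cx))
}

apply_rigid <- function(pts, transform) {
  sweep(pts %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Rigid point-cloud registration by iterative closest point
#'
#' Alternates nearest-neighbour matching with a least-squares (Kabsch) rigid
#' fit, after an initial centroid alignment. Rigid only -- no scaling.
#'
#' @param source,target point matrices (n x 3, mm), each with >= 3
#'   non-collinear points.
#' @param p a [segmentation_params()] supplying `icp_max_iter`, `icp_tol`,
#'   `max_points` and `seed`.
#' @return A list of class `rigid_transform`: `rotation` (3 x 3, det +1),
#'   `translation` (mm), `rmse` (mm), `iterations`, `converged`. Apply with
#'   `pts %*% t(rotation) + translation`.
#' @export
icp_register <- function(source, target, p = segmentation_params()) {
  src <- unclass(source); tgt <- unclass(target)
  if (nrow(src) < 3L || nrow(tgt) < 3L) stop("point clouds must have >= 3 points")
  if (nrow(src) > p$max_points) {
    src <- with_seed(p$seed, src[sort(sample(nrow(src), p$max_points)), , drop = FALSE])
  }
  if (nrow(tgt) > p$max_points) {
    tgt <- with_seed(p$seed + 1L, tgt[sort(sample(nrow(tgt), p$max_points)), , drop = FALSE])
  }
  tr <- list(rotation = diag(3),
             translation = colMeans(tgt) - colMeans(src))
  rmse_prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(p$icp_max_iter)) {
    moved <- apply_rigid(src, tr)
    nn <- cpp_nearest_idx(moved, tgt)
    matched <- tgt[nn, , drop = FALSE]
    tr <- kabsch(src, matched)
    moved <- apply_rigid(src, tr)
    rmse <- sqrt(mean(rowSums((moved - matched)^2)))
    if (is.finite(rmse_prev) &&
        abs(rmse_prev - rmse) <= p$icp_tol * max(rmse_prev, .Machine$double.eps)) {
      converged <- TRUE
      rmse_prev <- rmse
      break
    }
    rmse_prev <- rmse
  }
  if (!converged) warning("ICP did not converge; returning best transform so far")
  structure(list(rotation = tr$rotation, translation = tr$translation,
                 rmse = rmse_prev, iterations = it, converged = converged),
            class = "rigid_transform")
}

#' Select the ventricle component most similar to a reference mask
#'
#' Each candidate is converted to a point cloud, rigidly registered to the
#' reference cloud by ICP, and scored by the post-registration Hausdorff
#' distance; the candidate with the smallest distance wins (ties go to the
#' first, i.e. largest, candidate, with a message). The winning mask is
#' returned untransformed, in image space.
#'
#' @param candidates nonempty list of [binary_mask]s (largest first, as
#'   returned by [separate_components()]).
#' @param reference a [binary_mask] standing in for the atlas 4th-ventricle.
#' @param p a [segmentation_params()].
#' @return The selected [binary_mask], with attributes `hausdorff_mm`
#'   (per-candidate scores) and `selected` (index).
#' @export
select_ventricle <- function(candidates, reference, p = segmentation_params()) {
  if (length(candidates) == 0L) stop("no candidate components")
  ref_cloud <- mask_to_pointcloud(reference, max_points = p$max_points, seed = p$seed)
  scores <- vapply(candidates, function(cand) {
    cl <- mask_to_pointcloud(cand, max_points = p$max_points, seed = p$seed)
    tr <- tryCatch(icp_register(cl, ref_cloud, p), error = function(e) NULL)
    if (is.null(tr)) return(Inf)
    hausdorff(apply_rigid(unclass(cl), tr), ref_cloud,
              max_points = p$max_points, seed = p$seed)
  }, 0)
  if (all(!is.finite(scores))) stop("registration failed for every candidate")
  best <- which.min(scores)
  if (sum(scores == scores[best]) > 1L) {
    message("Hausdorff tie between candidates; keeping the largest")
    best <- which(scores == scores[best])[1L]
  }
  out <- candidates[[best]]
  attr(out, "hausdorff_mm") <- scores
  attr(out, "selected") <- best
  out
}

#' Active-contour refinement of a ventricle mask
#'
#' Runs a morphological two-phase (Chan-Vese) active contour on the
#' complement of the grayscale image (`max(image) - image`), initialized from
#' the given mask, for `ac_iterations` sweeps with `ac_smoothing` curvature
#' passes each.
#'
#' @param image a [volume_image] (same grid as `mask`).
#' @param mask nonempty initial [binary_mask].
#' @param p a [segmentation_params()].
#' @param complement evolve on the complemented image (default `TRUE`, the
#'   right choice for the dark ventricle).
#' @return Refined [binary_mask]; if the contour vanishes the input is
#'   returned with a warning.
#' @export
refine_active_contour <- function(image, mask, p = segmentation_params(),
                                  complement = TRUE) {
  stopifnot_same_geometry(image, mask, "image and mask")
  if (sum(mask$voxels) == 0L) stop("initial mask is empty")
  if (p$ac_iterations == 0L) return(mask)
  img <- if (complement) max(image$voxels) - image$voxels else image$voxels
  v <- cpp_chan_vese(as.vector(img), as.logical(mask$voxels), dim(img),
                     p$ac_iterations, p$ac_smoothing)
  out <- binary_mask(array(v, dim(img)), image$voxel_size_mm)
  if (sum(out$voxels) == 0L) {
    warning("active contour vanished; returning the initial mask")
    return(mask)
  }
  ov <- dice(out, mask)
  if (is.finite(ov) && ov < 0.5) {
    warning(sprintf("active contour drifted far from its initialization (Dice %.2f)", ov))
  }
  out
}
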