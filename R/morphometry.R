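#' Mask volume in cubic millimetres
#'
#' `Volume = NumberOfVoxels * VoxelSize^3`.
#'
#' @param mask a [binary_mask].
#' @return Scalar volume in mm^3 (0 for an empty mask).
#' @export
compute_volume <- function(mask) {
  sum(mask$voxels) * mask$voxel_size_mm^3
}

# run (intercept) count along an arbitrary lattice direction: number of
# foreground voxels whose predecessor along `step` is background/outside.
run_count_dir <- function(m, step) {
  d <- dim(m)
  prev <- array(FALSE, d)
  src_z <- seq_len(d[1]) - step[1]; src_y <- seq_len(d[2]) - step[2]
  src_x <- seq_len(d[3]) - step[3]
  okz <- src_z >= 1L & src_z <= d[1]
  oky <- src_y >= 1L & src_y <= d[2]
  okx <- src_x >= 1L & src_x <= d[3]
  prev[okz, oky, okx] <- m[src_z[okz], src_y[oky], src_x[okx]]
  sum(m & !prev)
}

#' Crofton-formula surface area of a binary mask, in mm^2
#'
#' Stereological estimate `S = 4 * sum_k (c_k / lambda_k) * chi_k`, where
#' `chi_k` is the number of foreground runs (intercepts, counted by run-length
#' encoding) along the family of discrete lines `L_k` parallel to direction k,
#' `lambda_k = d_k / v` is the line density (spacing `d_k` between neighbouring
#' voxels along k over the voxel volume `v`), and `c_k` is the direction
#' weight. The default uses the 3 axis-aligned directions with `c_k = 1/3`;
#' the 13-direction mode adds face and body diagonals with isotropic
#' discretized direction weights (normalized to sum to one).
#'
#' @param mask a [binary_mask].
#' @param directions 3 or 13.
#' @return Scalar surface area in mm^2 (0 for an empty mask).
#' @export
crofton_area <- function(mask, directions = 3) {
  if (!directions %in% c(3, 13)) stop("directions must be 3 or 13")
  m <- mask$voxels
  vs <- mask$voxel_size_mm
  if (sum(m) == 0L) return(0)
  axes <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  if (directions == 3) {
    chi <- vapply(axes, function(s) run_count_dir(m, s), 0)
    # c_k = 1/3, lambda_k = vs / vs^3  ->  4 * (1/3) * vs^2 * chi
    return(4 * sum(chi) * vs^2 / 3)
  }
  face <- list(c(1L, 1L, 0L), c(1L, -1L, 0L), c(1L, 0L, 1L),
               c(1L, 0L, -1L), c(0L, 1L, 1L), c(0L, 1L, -1L))
  body <- list(c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))
  dirs <- c(axes, face, body)
  # isotropic direction weights for the cubic 13-direction scheme
  # (Legland/Kieu/Devaux discretization), normalized to sum to 1
  w <- c(rep(0.04577789120476, 3), rep(0.03698062787608, 6),
         rep(0.03519563978232, 4))
  w <- w / sum(w)
  dist <- vs * sqrt(vapply(dirs, function(s) sum(s^2), 0))
  chi <- vapply(dirs, function(s) run_count_dir(m, s), 0)
  4 * sum(w * chi * vs^3 / dist)
}

#' Principal-axis outgrowth angle of a mask
#'
#' Fits the moment (PCA) ellipsoid of the foreground voxel coordinates: `A`
#' is their covariance matrix, eigenvalues are sorted in descending order and
#' the first eigenvector `v1` defines the model direction. The outgrowth
#' angle is `acos(|u . v1| / (|u||v1|)) * 180/pi`, folded to `[0, 90]` degrees
#' because the eigenvector sign is arbitrary.
#'
#' @param mask a [binary_mask] with >= 3 non-collinear foreground voxels.
#' @param u reference axis, `(z, y, x)` components. The default `(0, 0, 1)`
#'   is the lateral grid axis -- the normal of the sagittal plane, the
#'   "X-axis" of the defining formula in this package's axis convention.
#' @return A list of class `orientation_result`: `eigenvalues` (descending),
#'   `eigenvectors` (columns, unit), `reference_axis`, `angle_deg`, and
#'   `ambiguous` (`TRUE` when the two leading eigenvalues are nearly tied, so
#'   the principal axis is unstable).
#' @export
orientation_angle <- function(mask, u = c(0, 0, 1)) {
  idx <- which(mask$voxels)
  if (length(idx) < 3L) stop("need >= 3 foreground voxels")
  P <- index_to_coords(idx, dim(mask$voxels)) * mask$voxel_size_mm
  A <- stats::cov(P)
  e <- eigen(A, symmetric = TRUE)  # eigenvalues already descending
  if (e$values[2] <= .Machine$double.eps * e$values[1]) {
    stop("degenerate mask: foreground voxels are collinear")
  }
  uhat <- u / sqrt(sum(u^2))
  v1 <- e$vectors[, 1]
  cosang <- abs(sum(uhat * v1))  # fold to [0, 90]: eigenvector sign is arbitrary
  angle <- acos(pmin(1, cosang)) * 180 / pi
  ambiguous <- (e$values[1] - e$values[2]) < 1e-6 * e$values[1]
  if (ambiguous) warning("leading eigenvalues nearly tied: principal axis is ambiguous")
  structure(list(eigenvalues = e$values, eigenvectors = e$vectors,
                 reference_axis = uhat, angle_deg = angle,
                 ambiguous = ambiguous),
            class = "orientation_result")
}

#' Proportion of the plexus within the 4th ventricle
#'
#' `v_plexus / (v_plexus + v_ventricle)`.
#'
#' @param v_plexus,v_ventricle volumes in mm^3 (>= 0, not both 0).
#' @return Fraction in `[0, 1]`.
#' @export
proportion_in_ventricle <- function(v_plexus, v_ventricle) {
  if (v_plexus < 0 || v_ventricle < 0) stop("volumes must be >= 0")
  if (v_plexus + v_ventricle <= 0) stop("volumes sum to zero")
  v_plexus / (v_plexus + v_ventricle)
}

#' Split a mask by a plane into rostral and caudal parts
#'
#' Partition by the sign of the distance to the plane; voxels with
#' non-negative signed distance go to the rostral part, so the two volumes
#' sum exactly to the total.
#'
#' @param mask a [binary_mask].
#' @param point plane point, mm, `(z, y, x)`.
#' @param normal plane normal (nonzero), `(z, y, x)`; it points towards the
#'   rostral side.
#' @return List with `rostral` and `caudal` [binary_mask]s.
#' @export
split_by_plane <- function(mask, point, normal) {
  if (sum(normal^2) == 0) stop("plane normal must be nonzero")
  d <- dim(mask$voxels)
  idx <- which(mask$voxels)
  rostral <- array(FALSE, d); caudal <- array(FALSE, d)
  if (length(idx) > 0L) {
    P <- index_to_coords(idx, d) * mask$voxel_size_mm
    s <- as.vector(sweep(P, 2, point) %*% normal)
    rostral[idx[s >= 0]] <- TRUE
    caudal[idx[s < 0]] <- TRUE
  }
  list(rostral = binary_mask(rostral, mask$voxel_size_mm),
       caudal = binary_mask(caudal, mask$voxel_size_mm))
}

#' Lateral extent, branch length/angle and rostrocaudal-plane measures
#'
#' Automated analogue of the manual transverse-plane measurements: the centre
#' is the plexus centroid projected onto the sagittal midline plane; each
#' branch length is the maximum in-plane (transverse, i.e. ignoring the stack
#' axis) distance from the centre to a foreground voxel on that side of the
#' midline; each branch angle is measured between the brain's central axis
#' (the in-plane axis lying in the midline plane) and the centre-to-extremal
#' ray. `total_length` is the sum of the two lateral extents;
#' `central_length` subtracts, per side, the extent beyond the ventricle-body
#' bound; `ventricle_length` applies the same extent measurement to the
#' ventricle mask. These are deterministic geometric procedures, not replays
#' of interactive click measurements.
#'
#' @param mask plexus [binary_mask].
#' @param ventricle ventricle [binary_mask] on the same grid.
#' @param midline_point point on the sagittal midline plane, mm `(z, y, x)`;
#'   default: the ventricle centroid.
#' @param midline_normal unit normal of the midline plane (the lateral axis);
#'   default `(0, 0, 1)`.
#' @param body_bound_mm lateral distance from the midline at which the
#'   ventricle body ends and the recesses begin; branches are counted beyond
#'   it. Default: `body_bound_frac` of the ventricle's lateral half-extent.
#' @param body_bound_frac fraction used when `body_bound_mm` is `NULL`.
#' @return A list with `left_length_mm`, `right_length_mm`, `left_angle_deg`,
#'   `right_angle_deg`, `central_length_mm`, `total_length_mm`,
#'   `ventricle_length_mm` (angles are `NaN` and flagged when a side is
#'   empty).
#' @export
lateral_measures <- function(mask, ventricle, midline_point = NULL,
                             midline_normal = c(0, 0, 1),
                             body_bound_mm = NULL, body_bound_frac = 0.6) {
  stopifnot_same_geometry(mask, ventricle, "plexus and ventricle masks")
  n <- midline_normal / sqrt(sum(midline_normal^2))
  d <- dim(mask$voxels)
  vs <- mask$voxel_size_mm
  vent_pts <- index_to_coords(which(ventricle$voxels), d) * vs
  if (nrow(vent_pts) == 0L) stop("ventricle mask is empty")
  if (is.null(midline_point)) midline_point <- colMeans(vent_pts)

  # in-plane (transverse) extent measurement shared by both masks
  extent_by_side <- function(P) {
    ctr <- colMeans(P)
    ctr <- ctr - sum((ctr - midline_point) * n) * n  # project to midline
    side <- as.vector(sweep(P, 2, midline_point) %*% n)
    disp <- sweep(P, 2, ctr)
    disp[, 1] <- 0  # transverse plane: drop the stack (rostrocaudal) axis
    dist <- sqrt(rowSums(disp^2))
    # central axis: in-plane direction lying in the midline plane
    ax <- c(0, 1, 0) - sum(c(0, 1, 0) * n) * n
    ax[1] <- 0
    ax <- if (sum(ax^2) > 0) ax / sqrt(sum(ax^2)) else c(0, 1, 0)
    one_side <- function(sel) {
      if (!any(sel)) return(list(length = 0, angle = NaN))
      i <- which(sel)[which.max(dist[sel])]
      len <- dist[i]
      ray <- disp[i, ]
      ang <- if (len > 0) acos(pmin(1, pmax(-1, sum(ray * ax) / len))) * 180 / pi else NaN
      list(length = len, angle = ang)
    }
    list(left = one_side(side < 0), right = one_side(side > 0))
  }

  pl_pts <- index_to_coords(which(mask$voxels), d) * vs
  if (nrow(pl_pts) == 0L) {
    return(list(left_length_mm = 0, right_length_mm = 0,
                left_angle_deg = NaN, right_angle_deg = NaN,
                central_length_mm = 0, total_length_mm = 0,
                ventricle_length_mm = {
                  ve <- extent_by_side(vent_pts)
                  ve$left$length + ve$right$length
                }))
  }
  pe <- extent_by_side(pl_pts)
  ve <- extent_by_side(vent_pts)
  ventricle_length <- ve$left$length + ve$right$length
  if (is.null(body_bound_mm)) {
    body_bound_mm <- body_bound_frac * max(ve$left$length, ve$right$length)
  }
  total <- pe$left$length + pe$right$length
  beyond <- max(0, pe$left$length - body_bound_mm) +
    max(0, pe$right$length - body_bound_mm)
  list(left_length_mm = pe$left$length, right_length_mm = pe$right$length,
       left_angle_deg = pe$left$angle, right_angle_deg = pe$right$angle,
       central_length_mm = total - beyond, total_length_mm = total,
       ventricle_length_mm = ventricle_length)
}

#' Morphometric criterion panel for one sample
#'
#' Runs the full panel on a plexus/ventricle mask pair: volume, Crofton
#' surface area, outgrowth angle, ventricle proportion, rostrocaudal split
#' volumes and the lateral-extent measures. Any failing criterion is recorded
#' as `NaN` with a log entry rather than aborting the panel.
#'
#' @param plexus,ventricle [binary_mask]s on the same grid.
#' @param config optional list: `reference_axis` (for the outgrowth angle),
#'   `split_point`/`split_normal` (rostrocaudal plane; defaults to the
#'   transverse plane through the plexus centroid), `midline_point`,
#'   `midline_normal`, `body_bound_mm`, `crofton_directions`.
#' @param sample sample identifier carried into the report.
#' @return A list of class `morphometry_report` (see [write_report()] for the
#'   serialized column set) with attribute `log` listing any failures.
#' @export
build_report <- function(plexus, ventricle, config = list(), sample = NA_character_) {
  stopifnot_same_geometry(plexus, ventricle, "plexus and ventricle masks")
  log <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log <<- c(log, sprintf("%s: %s", name, conditionMessage(e)))
      NaN
    })
  }
  cfg <- utils::modifyList(list(
    reference_axis = c(0, 0, 1),
    split_point = NULL, split_normal = c(1, 0, 0),
    midline_point = NULL, midline_normal = c(0, 0, 1),
    body_bound_mm = NULL, crofton_directions = 3
  ), config)

  vol <- grab("volume", compute_volume(plexus))
  vvol <- grab("ventricle_volume", compute_volume(ventricle))
  area <- grab("surface_area", crofton_area(plexus, cfg$crofton_directions))
  ang <- grab("outgrowth_angle", orientation_angle(plexus, cfg$reference_axis)$angle_deg)
  prop <- grab("proportion", proportion_in_ventricle(vol, vvol))

  split_point <- cfg$split_point
  if (is.null(split_point)) {
    idx <- which(plexus$voxels)
    split_point <- if (length(idx) > 0L) {
      colMeans(index_to_coords(idx, dim(plexus$voxels))) * plexus$voxel_size_mm
    } else c(0, 0, 0)
  }
  halves <- grab("split", split_by_plane(plexus, split_point, cfg$split_normal))
  rostral <- if (is.list(halves)) compute_volume(halves$rostral) else NaN
  caudal <- if (is.list(halves)) compute_volume(halves$caudal) else NaN

  lat <- grab("lateral_measures",
              lateral_measures(plexus, ventricle,
                               midline_point = cfg$midline_point,
                               midline_normal = cfg$midline_normal,
                               body_bound_mm = cfg$body_bound_mm))
  if (!is.list(lat)) {
    lat <- list(left_length_mm = NaN, right_length_mm = NaN,
                left_angle_deg = NaN, right_angle_deg = NaN,
                central_length_mm = NaN, total_length_mm = NaN,
                ventricle_length_mm = NaN)
  }
  rep <- c(list(sample = sample, volume_mm3 = vol, surface_area_mm2 = area,
                outgrowth_angle_deg = ang, ventricle_volume_mm3 = vvol,
                proportion = prop, rostral_volume_mm3 = rostral,
                caudal_volume_mm3 = caudal), lat)
  structure(rep, class = "morphometry_report", log = log)
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %s\n", x$sample))
  for (f in report_fields()) cat(sprintf("  %-22s %.6g\n", f, x[[f]]))
  invisible(x)
}
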