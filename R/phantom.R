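#' Phantom specification
#'
#' Describes a synthetic embryo-head micro-CT volume: a mid-intensity tissue
#' block containing a dark CSF-filled 4th-ventricle cavity (a bent elliptical
#' slab with two lateral recesses) and a bright, branched choroid plexus lying
#' inside the cavity and touching its wall. Defaults emulate the contrast
#' regime the segmentation pipeline assumes: plexus 200, tissue 120,
#' ventricle 40 intensity units with additive Gaussian noise sigma 10, i.e.
#' plexus-vs-tissue contrast-to-noise ratio 8, on a 128^3 grid at 4 um voxels.
#'
#' @param grid_shape integer 3-vector, voxels per axis `(z, y, x)`; each >= 32.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tissue_level,ventricle_level,plexus_level mean intensities, with
#'   `plexus_level > tissue_level > ventricle_level >= 0`.
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param stage developmental stage, one of `"E13.5"`, `"E15.5"`, `"E17.5"`;
#'   controls how far the lateral recesses (and default branches) extend.
#' @param branch_angle_deg tilt of each lateral branch away from the
#'   transverse mid-plane, degrees.
#' @param branch_length_frac branch tip position as a fraction of the
#'   ventricle half-width (body plus recess); `NULL` picks a stage default
#'   (0.55 / 0.85 / 1.0 for E13.5 / E15.5 / E17.5).
#' @param decoy include a second dark component (a stand-in for the rest of
#'   the ventricular system) joined to the cavity by a thin false connection.
#' @param seed RNG seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_size_mm = 0.004,
                         tissue_level = 120,
                         ventricle_level = 40,
                         plexus_level = 200,
                         noise_sigma = 10,
                         stage = c("E13.5", "E15.5", "E17.5"),
                         branch_angle_deg = 10,
                         branch_length_frac = NULL,
                         decoy = TRUE,
                         seed = 1L) {
  stage <- match.arg(stage)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L)) {
    stop("grid_shape must have 3 entries, each >= 32, to contain the ventricle template")
  }
  if (!(plexus_level > tissue_level && tissue_level > ventricle_level &&
        ventricle_level >= 0)) {
    stop("intensity levels must satisfy plexus > tissue > ventricle >= 0")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(branch_length_frac)) {
    branch_length_frac <- switch(stage, E13.5 = 0.55, E15.5 = 0.85, E17.5 = 1.0)
  }
  if (branch_length_frac < 0 || branch_length_frac > 1) {
    stop("branch_length_frac must lie in [0, 1]")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 tissue_level = tissue_level, ventricle_level = ventricle_level,
                 plexus_level = plexus_level, noise_sigma = noise_sigma,
                 stage = stage, branch_angle_deg = branch_angle_deg,
                 branch_length_frac = branch_length_frac,
                 decoy = isTRUE(decoy), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Coordinate arrays (0-based voxel indices) for a grid.
grid_coords <- function(d) {
  list(Z = slice.index(array(0L, d), 1L) - 1L,
       Y = slice.index(array(0L, d), 2L) - 1L,
       X = slice.index(array(0L, d), 3L) - 1L)
}

# Deterministic phantom geometry. All sizes are fixed fractions of the grid;
# they were chosen once to reproduce the topology the segmentation exploits
# (bright plexus enclosed in a dark cavity whose gap a modest morphological
# closing can fill) and are not anatomical measurements.
phantom_geometry <- function(spec) {
  d <- spec$grid_shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  cz <- (nz - 1) / 2; cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  ax <- 0.26 * nx; ay <- 0.085 * ny; az <- 0.17 * nz
  bend <- 0.07 * ny
  rec_frac <- switch(spec$stage, E13.5 = 0.5, E15.5 = 1.0, E17.5 = 1.4)
  L_rec <- rec_frac * 0.14 * nx
  rr <- 0.055 * ny              # recess radius
  rp <- 0.035 * ny              # plexus ridge radius
  tanA <- tan(spec$branch_angle_deg * pi / 180)
  u_tip <- spec$branch_length_frac * (ax + L_rec) / ax

  co <- grid_coords(d)
  Z <- co$Z; Y <- co$Y; X <- co$X
  u <- (X - cx) / ax
  au <- abs(u)
  ycen <- cy + bend * pmin(u^2, 1)

  body <- ((Z - cz) / az)^2 + ((Y - ycen) / ay)^2 + u^2 <= 1

  # lateral recesses: cylinders along x, tilted by the branch angle, starting
  # inside the body so the branch tubes they carry stay enclosed in CSF
  dz_path <- tanA * pmax(0, au * ax - 0.55 * ax)
  recess <- (au >= 0.5 & au * ax <= ax + L_rec) &
    ((Z - (cz + dz_path))^2 + (Y - (cy + bend))^2 <= rr^2)

  # central ridge: suspended in CSF two voxels off the ventral wall, attached
  # to it by a thin fin (the tela choroidea root), so the lumen wraps the
  # plexus body everywhere except that narrow attachment
  y_ridge <- ycen + ay - rp - 2
  ridge <- au <= 0.55 &
    ((Z - cz) / (1.5 * rp))^2 + ((Y - y_ridge) / rp)^2 <= 1
  fin <- abs(X - cx) <= 1.2 & abs(Z - cz) <= rp &
    Y >= y_ridge & Y <= ycen + ay
  ridge <- (ridge | fin) & body

  # branch tubes: blend from the ridge centre onto the recess axis, taper
  w <- pmin(1, pmax(0, (au - 0.45) / 0.1))
  y_path <- (1 - w) * y_ridge + w * (cy + bend)
  r_tube <- rp * (0.8 - 0.3 * pmin(1, pmax(0, (au - 0.45) / max(u_tip - 0.45, 1e-9))))
  tube <- (au >= 0.45 & au <= u_tip) &
    ((Z - (cz + dz_path))^2 + (Y - y_path)^2 <= r_tube^2)

  plexus <- (ridge | tube) & (body | recess)
  cavity <- body | recess

  decoy <- array(FALSE, d)
  bridge <- array(FALSE, d)
  if (spec$decoy) {
    dy0 <- cy - 0.22 * ny
    decoy <- ((Z - cz) / (0.10 * nz))^2 + ((Y - dy0) / (0.07 * ny))^2 +
      ((X - cx) / (0.10 * nx))^2 <= 1
    bridge <- ((Z - cz)^2 + (X - cx)^2 <= 1.4^2) & (Y >= dy0) & (Y <= cy)
  }

  list(cavity = cavity, plexus = plexus, decoy = decoy, bridge = bridge,
       params = list(cz = cz, cy = cy, cx = cx, ax = ax, ay = ay, az = az,
                     bend = bend, rr = rr, rp = rp, L_rec = L_rec,
                     u_tip = u_tip, tanA = tanA))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic embryo-head micro-CT phantom
#'
#' Builds the grayscale volume plus ground-truth masks described by a
#' [phantom_spec()]: the image equals `tissue_level` everywhere,
#' `ventricle_level` inside the CSF-filled cavity (and the optional decoy
#' component plus its thin false connection), and `plexus_level` on the
#' branched plexus body; iid Gaussian noise is then added and the result
#' clipped at zero. Identical specs (including `seed`) give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `image` ([volume_image]),
#'   `ventricle_truth` and `plexus_truth` (disjoint [binary_mask]s; the
#'   ventricle truth is the CSF lumen, i.e. cavity minus plexus, excluding the
#'   decoy), `tissue_truth` (the mid-intensity surrounding tissue, the
#'   comparison region for contrast-to-noise measurements), `landmark_truth`
#'   (a 10-point [landmark_config] in mm) and `spec`.
#' @export
generate_embryo_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$grid_shape
  g <- phantom_geometry(spec)

  img <- array(spec$tissue_level, d)
  dark <- (g$cavity | g$decoy | g$bridge) & !g$plexus
  img[dark] <- spec$ventricle_level
  img[g$plexus] <- spec$plexus_level
  if (spec$noise_sigma > 0) {
    img <- img + with_seed(spec$seed, array(rnorm(prod(d), 0, spec$noise_sigma), d))
    img <- pmax(img, 0)
  }

  lumen <- g$cavity & !g$plexus
  list(
    image = volume_image(img, spec$voxel_size_mm),
    ventricle_truth = binary_mask(lumen, spec$voxel_size_mm),
    plexus_truth = binary_mask(g$plexus, spec$voxel_size_mm),
    tissue_truth = binary_mask(!dark & !g$plexus, spec$voxel_size_mm),
    landmark_truth = phantom_landmarks(spec),
    spec = spec
  ) |> structure(class = "phantom")
}

#' Ground-truth landmark configuration of a phantom
#'
#' Ten deterministic, anatomically ordered points on the plexus template
#' (centre, rostral/caudal ridge ends, left/right ridge-branch junctions,
#' mid-branch points, branch tips and the ventral wall contact), in mm,
#' coordinate order `(z, y, x)`.
#'
#' @param spec a [phantom_spec()].
#' @return A [landmark_config()] with 10 points.
#' @export
phantom_landmarks <- function(spec) {
  p <- phantom_geometry(spec)$params
  vs <- spec$voxel_size_mm
  path_point <- function(u) {
    x <- u * p$ax
    w <- min(1, max(0, (u - 0.45) / 0.1))
    y <- (1 - w) * (p$cy + p$bend * min(u^2, 1) + p$ay - p$rp - 2) +
      w * (p$cy + p$bend)
    z <- p$cz + p$tanA * max(0, x - 0.55 * p$ax)
    c(z, y, x)
  }
  yr <- p$cy + p$ay - p$rp - 2      # ridge centre height at the midline
  junc <- path_point(0.55)
  mid <- path_point((0.55 + p$u_tip) / 2)
  tip <- path_point(p$u_tip)
  flip_x <- function(q) c(q[1], q[2], -q[3])

  pts <- rbind(
    c(p$cz,              yr, 0),            # 1 ridge centre
    c(p$cz - 1.5 * p$rp, yr, 0),            # 2 rostral ridge end
    c(p$cz + 1.5 * p$rp, yr, 0),            # 3 caudal ridge end
    flip_x(junc), junc,                     # 4/5 left & right junctions
    flip_x(mid), mid,                       # 6/7 left & right mid-branch
    flip_x(tip), tip,                       # 8/9 left & right branch tips
    c(p$cz, p$cy + p$ay, 0)                 # 10 ventral wall contact
  )
  pts[, 3] <- pts[, 3] + p$cx
  cfg <- landmark_config(pts * vs, label = paste0("phantom_", spec$stage))
  colnames(cfg$points) <- c("z", "y", "x")
  cfg
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; `axis` is normalized internally. Components follow the
#' package-wide `(z, y, x)` coordinate order.
#'
#' @param axis numeric 3-vector, rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Synthetic reference mask of the 4th ventricle
#'
#' Stands in for an atlas-derived reference: the phantom's ventricle truth
#' under a small rigid perturbation (rotation about the mask centroid plus a
#' voxel translation), optionally grown or shrunk by one voxel.
#'
#' @param spec a [phantom_spec()].
#' @param rotation_deg rotation angle in degrees (about `rotation_axis`
#'   through the mask centroid).
#' @param rotation_axis rotation axis, `(z, y, x)` components.
#' @param translation_vox translation in voxels, `(z, y, x)`.
#' @param boundary one of `-1` (erode by 1 voxel), `0`, `1` (dilate by 1).
#' @return A [binary_mask] on the phantom grid.
#' @export
generate_reference_ventricle <- function(spec, rotation_deg = 0,
                                         rotation_axis = c(1, 0, 0),
                                         translation_vox = c(0, 0, 0),
                                         boundary = 0L) {
  g <- phantom_geometry(spec)
  lumen <- g$cavity & !g$plexus
  d <- spec$grid_shape
  out <- transform_mask_rigid(lumen, rotation_matrix(rotation_axis, rotation_deg),
                              translation_vox)
  m <- binary_mask(out, spec$voxel_size_mm)
  if (boundary > 0) m <- mask_dilate(m, 1)
  if (boundary < 0) m <- mask_erode(m, 1)
  m
}

# Rigidly move a logical array: rotation R about the foreground centroid,
# then translation (voxels). Nearest-neighbour resampling by inverse mapping
# over the whole grid.
transform_mask_rigid <- function(vox, R, t_vox) {
  d <- dim(vox)
  if (identical(R, diag(3)) && all(t_vox == 0)) return(vox)
  idx <- which(vox)
  if (length(idx) == 0L) return(vox)
  ctr <- colMeans(index_to_coords(idx, d))
  co <- grid_coords(d)
  P <- cbind(as.vector(co$Z), as.vector(co$Y), as.vector(co$X))
  # inverse map: source = R^T (target - centroid - t) + centroid
  S <- sweep(P, 2, ctr + t_vox) %*% R  # (P - c - t) %*% R == t(R^T %*% ...)
  S <- sweep(S, 2, ctr, `+`)
  si <- round(S) + 1
  ok <- si[, 1] >= 1 & si[, 1] <= d[1] &
        si[, 2] >= 1 & si[, 2] <= d[2] &
        si[, 3] >= 1 & si[, 3] <= d[3]
  out <- array(FALSE, d)
  lin <- si[ok, 1] + d[1] * (si[ok, 2] - 1) + d[1] * d[2] * (si[ok, 3] - 1)
  out[ok] <- vox[lin]
  out
}

# 0-based (z, y, x) voxel indices of linear indices
index_to_coords <- function(idx, d) {
  idx0 <- idx - 1L
  z <- idx0 %% d[1]
  y <- (idx0 %/% d[1]) %% d[2]
  x <- idx0 %/% (d[1] * d[2])
  cbind(z = z, y = y, x = x)
}

#' Generate noisy, similarity-transformed landmark sets
#'
#' Each sample is `base` plus iid Gaussian landmark noise, then a random
#' similarity transform (scale, rotation, translation) drawn uniformly within
#' the given bounds. Used as a fixture generator for Procrustes analyses.
#'
#' @param n_samples number of configurations (>= 1).
#' @param k landmarks per configuration (>= 3).
#' @param noise_sigma_mm Gaussian landmark noise SD in mm.
#' @param scale_range length-2 vector of uniform scale bounds.
#' @param rotation_deg_max maximum rotation magnitude, degrees.
#' @param translation_mm_max maximum per-axis translation magnitude, mm.
#' @param seed RNG seed.
#' @param base optional [landmark_config()] template; the default is the
#'   10-point phantom landmark truth when `k == 10`, otherwise `k` points on
#'   a helix of 1 mm radius.
#' @return List of `n_samples` [landmark_config()] objects.
#' @export
generate_landmark_sets <- function(n_samples, k = 10L, noise_sigma_mm = 0.02,
                                   scale_range = c(0.9, 1.1),
                                   rotation_deg_max = 20,
                                   translation_mm_max = 0.5,
                                   seed = 1L, base = NULL) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (k < 3L) stop("k must be >= 3")
  if (is.null(base)) {
    base <- if (k == 10L) phantom_landmarks(phantom_spec()) else {
      t <- seq(0, 2 * pi, length.out = k)
      landmark_config(cbind(cos(t), sin(t), seq(0, 1, length.out = k)),
                      label = "helix_base")
    }
  }
  if (nrow(base$points) != k) stop("base configuration must have k landmarks")
  with_seed(seed, {
    lapply(seq_len(n_samples), function(i) {
      pts <- base$points + matrix(rnorm(k * 3, 0, noise_sigma_mm), k, 3)
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_matrix(ax, runif(1, -rotation_deg_max, rotation_deg_max))
      s <- runif(1, scale_range[1], scale_range[2])
      tr <- runif(3, -translation_mm_max, translation_mm_max)
      landmark_config(sweep(s * (pts %*% t(R)), 2, tr, `+`),
                      label = sprintf("sample_%02d", i))
    })
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> stage %s, grid %s, noise sigma %.3g\n",
              x$spec$stage, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$noise_sigma))
  invisible(x)
}
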