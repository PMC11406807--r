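centroid_size <- function(pts) sqrt(sum(scale(pts, scale = FALSE)^2))

normalize_config <- function(pts, scale = TRUE) {
  ctr <- sweep(pts, 2, colMeans(pts))
  if (scale) {
    cs <- sqrt(sum(ctr^2))
    if (cs <= 0) stop("degenerate configuration: all landmarks coincide")
    ctr <- ctr / cs
  }
  ctr
}

config_points <- function(x) {
  if (inherits(x, "landmark_config")) x$points else as.matrix(x)
}

#' Pairwise (ordinary) Procrustes alignment
#'
#' Centres `y`, optimally rotates (orthogonal Procrustes via SVD, reflections
#' disallowed) and -- when `allow_scale` -- scales it onto `x`. The Procrustes
#' distance is the sum of squared landmark-wise differences between `x` and
#' the aligned `y`.
#'
#' @param x,y [landmark_config()]s (or K x 3 matrices) with equal K.
#' @param allow_scale remove the size difference as well.
#' @return List with `aligned_y` (K x 3), `distance`, `rotation`, `scale`,
#'   `translation`.
#' @export
procrustes_pair <- function(x, y, allow_scale = TRUE) {
  X <- config_points(x); Y <- config_points(y)
  if (!all(dim(X) == dim(Y))) stop("configurations must have the same landmark count")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (sum(Xc^2) <= 0 || sum(Yc^2) <= 0) {
    stop("degenerate configuration: all landmarks coincide")
  }
  M <- crossprod(Yc, Xc)  # t(Yc) %*% Xc
  s <- svd(M)
  W <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  R <- s$u %*% W %*% t(s$v)     # Yc %*% R approximates Xc
  sc <- if (allow_scale) sum(diag(W) * s$d) / sum(Yc^2) else 1
  aligned <- sc * Yc %*% R
  aligned <- sweep(aligned, 2, cx, `+`)
  list(aligned_y = aligned, distance = sum((X - aligned)^2),
       rotation = R, scale = sc, translation = cx - cy)
}

#' Generalized Procrustes Analysis of landmark configurations
#'
#' Iterative alignment removing translation, rotation and (by default) scale:
#' (1) the first configuration seeds the mean; (2) every configuration is
#' aligned to the mean; (3) the mean is re-estimated from the aligned set
#' (re-centred, and re-normalized to unit centroid size when scale is
#' removed); (4) repeat from (2) until the mean displacement drops below
#' `tol` or `max_iter` is reached. Per-sample Procrustes distances are the
#' sums of squared landmark differences to the converged mean.
#'
#' @param configs list of >= 2 [landmark_config()]s with equal landmark count.
#' @param tol convergence tolerance on the mean displacement (mm when scale
#'   is kept; shape units otherwise).
#' @param max_iter iteration cap.
#' @param scale remove size by unit-centroid-size normalization (default).
#' @return A list of class `gpa_result`: `mean_config` (K x 3, centred at the
#'   origin), `aligned` (list of K x 3), `distances`, `labels`, `iterations`,
#'   `converged`.
#' @export
generalized_procrustes <- function(configs, tol = 1e-6, max_iter = 100L,
                                   scale = TRUE) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  pts <- lapply(configs, config_points)
  k <- nrow(pts[[1L]])
  if (!all(vapply(pts, nrow, 0L) == k)) stop("all configurations must share the landmark count")
  norm <- lapply(pts, normalize_config, scale = scale)

  mean_cfg <- norm[[1L]]
  aligned <- norm
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    aligned <- lapply(norm, function(p) {
      procrustes_pair(mean_cfg, p, allow_scale = scale)$aligned_y
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- normalize_config(new_mean, scale = scale)
    disp <- sqrt(mean((new_mean - mean_cfg)^2))
    mean_cfg <- new_mean
    if (disp < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("GPA did not converge within max_iter")
  # final pass against the converged mean
  aligned <- lapply(norm, function(p) {
    procrustes_pair(mean_cfg, p, allow_scale = scale)$aligned_y
  })
  distances <- vapply(aligned, function(a) sum((a - mean_cfg)^2), 0)
  labels <- vapply(configs, function(cfg) {
    if (inherits(cfg, "landmark_config")) cfg$label else NA_character_
  }, "")
  structure(list(mean_config = mean_cfg, aligned = aligned,
                 distances = distances, labels = labels,
                 iterations = it, converged = converged),
            class = "gpa_result")
}

#' Procrustes distances against a fixed reference mean
#'
#' Single-pass alignment of each configuration to a fixed reference (e.g. the
#' converged wild-type mean), with no mean re-estimation -- the mode used for
#' scoring mutant samples.
#'
#' @param configs list of >= 1 [landmark_config()]s.
#' @param reference_mean reference [landmark_config()] (same landmark count).
#' @param scale remove size (must match how the reference was built).
#' @return A `gpa_result` with `iterations = 1`, `converged = TRUE`.
#' @export
gpa_against_reference <- function(configs, reference_mean, scale = TRUE) {
  if (length(configs) < 1L) stop("need at least 1 configuration")
  ref <- normalize_config(config_points(reference_mean), scale = scale)
  pts <- lapply(configs, config_points)
  if (!all(vapply(pts, nrow, 0L) == nrow(ref))) {
    stop("all configurations must share the reference landmark count")
  }
  aligned <- lapply(pts, function(p) {
    procrustes_pair(ref, normalize_config(p, scale = scale),
                    allow_scale = scale)$aligned_y
  })
  distances <- vapply(aligned, function(a) sum((a - ref)^2), 0)
  labels <- vapply(configs, function(cfg) {
    if (inherits(cfg, "landmark_config")) cfg$label else NA_character_
  }, "")
  structure(list(mean_config = ref, aligned = aligned, distances = distances,
                 labels = labels, iterations = 1L, converged = TRUE),
            class = "gpa_result")
}

#' Select an ordered subset of landmarks
#'
#' Keeps the given landmark indices (1-based, in the given order) so
#' downstream Procrustes analyses run on the subset -- e.g. restricting a
#' mutant comparison to the landmarks that remain identifiable.
#'
#' @param cfg a [landmark_config()].
#' @param indices ordered vector of >= 3 distinct 1-based indices.
#' @return A [landmark_config()] with `length(indices)` landmarks.
#' @export
subset_landmarks <- function(cfg, indices) {
  k <- nrow(cfg$points)
  indices <- as.integer(indices)
  if (any(is.na(indices)) || any(indices < 1L) || any(indices > k)) {
    stop("landmark indices out of range 1..", k)
  }
  if (anyDuplicated(indices)) stop("duplicate landmark indices")
  if (length(indices) < 3L) stop("need at least 3 landmarks")
  landmark_config(cfg$points[indices, , drop = FALSE], label = cfg$label)
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("<gpa_result> %d samples, %d landmarks, %s after %d iteration(s)\n",
              length(x$distances), nrow(x$mean_config),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  Procrustes distances:", format(signif(x$distances, 4)), "\n")
  invisible(x)
}
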