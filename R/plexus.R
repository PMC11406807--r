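#' Plexus segmentation parameter block
#'
#' Structuring-element sizes and thresholds for plexus extraction. The
#' defaults are tuned to the bundled phantom scale and are fully exposed; the
#' high-intensity threshold defaults to Otsu restricted to the candidate
#' region.
#'
#' @param closing_radius ball radius (voxels) of the gap-filling closing.
#' @param range_window odd window (voxels per axis) of the local range filter.
#' @param opening_radius ball radius of the tissue-shedding opening.
#' @param high_intensity_method `"otsu_within_mask"` or `"percentile"`.
#' @param high_intensity_percentile percentile (of intensities inside the
#'   candidate region) for the percentile method.
#' @param keep_k how many largest connected components form the primary mask.
#' @param ac_iterations,ac_smoothing final active-contour sweeps/smoothing.
#' @param ac_on_complement run the final E13.5 active contour on the
#'   complemented image instead of the raw image. The plexus is bright, so
#'   the raw image is the default.
#' @param connectivity component connectivity (6 or 26).
#' @return A list of class `plexus_params`.
#' @export
plexus_params <- function(closing_radius = 5L, range_window = 3L,
                          opening_radius = 2L,
                          high_intensity_method = c("otsu_within_mask", "percentile"),
                          high_intensity_percentile = 50,
                          keep_k = 1L,
                          ac_iterations = 20L, ac_smoothing = 1L,
                          ac_on_complement = FALSE,
                          connectivity = 26L) {
  high_intensity_method <- match.arg(high_intensity_method)
  if (closing_radius < 1L || opening_radius < 1L) stop("radii must be >= 1")
  if (range_window %% 2L != 1L) stop("range_window must be odd")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(closing_radius = as.integer(closing_radius),
                 range_window = as.integer(range_window),
                 opening_radius = as.integer(opening_radius),
                 high_intensity_method = high_intensity_method,
                 high_intensity_percentile = high_intensity_percentile,
                 keep_k = as.integer(keep_k),
                 ac_iterations = as.integer(ac_iterations),
                 ac_smoothing = as.integer(ac_smoothing),
                 ac_on_complement = isTRUE(ac_on_complement),
                 connectivity = as.integer(connectivity)),
            class = "plexus_params")
}

high_threshold <- function(values, p) {
  if (p$high_intensity_method == "otsu_within_mask") {
    otsu_threshold(values)
  } else {
    as.numeric(stats::quantile(values, p$high_intensity_percentile / 100))
  }
}

keep_largest <- function(mask, k, connectivity) {
  lab <- label_components(mask, connectivity)
  sizes <- attr(lab, "sizes")
  if (length(sizes) == 0L) return(mask)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(k, length(sizes)))]
  binary_mask(array(lab %in% keep, dim(mask$voxels)), mask$voxel_size_mm)
}

#' Primary HbChP mask from the segmented ventricle
#'
#' Morphological closing of the ventricular-system mask fills the gap the
#' bright plexus occupies; subtracting the original mask isolates that gap
#' region, inside which the high-intensity voxels are kept and the largest
#' connected component(s) selected. Works for every stage; for E13.5 it seeds
#' the fully automatic extension, for E15.5/E17.5 it is the export for manual
#' branch segmentation.
#'
#' @param image a [volume_image].
#' @param ventricle nonempty ventricle [binary_mask] on the same grid.
#' @param p a [plexus_params()].
#' @return A [binary_mask] disjoint from the ventricle lumen; empty with a
#'   warning when the closing fills no gaps.
#' @export
primary_mask <- function(image, ventricle, p = plexus_params()) {
  stopifnot_same_geometry(image, ventricle, "image and ventricle")
  if (sum(ventricle$voxels) == 0L) stop("ventricle mask is empty")
  closed <- mask_close(ventricle, p$closing_radius)
  gap <- binary_mask(closed$voxels & !ventricle$voxels, image$voxel_size_mm)
  if (sum(gap$voxels) == 0L) {
    warning("closing filled no gaps; no plexus candidate region")
    return(gap)
  }
  thr <- high_threshold(image$voxels[gap$voxels], p)
  if (is.na(thr)) thr <- -Inf  # constant gap region: keep it all
  high <- binary_mask(gap$voxels & image$voxels >= thr, image$voxel_size_mm)
  if (sum(high$voxels) == 0L) {
    warning("no high-intensity voxels inside the gap region")
    return(high)
  }
  out <- keep_largest(high, p$keep_k, p$connectivity)
  attr(out, "threshold") <- thr
  out
}

#' Local range filter (per-voxel max - min over a cubic window)
#'
#' @param image a [volume_image].
#' @param window odd window edge length in voxels.
#' @return A [volume_image] of range values (>= 0 everywhere).
#' @export
local_range <- function(image, window = 3L) {
  if (window %% 2L != 1L) stop("window must be odd")
  d <- dim(image$voxels)
  if (any(window > d)) stop("window does not fit within the image")
  volume_image(array(cpp_local_range3(as.vector(image$voxels), d, as.integer(window)), d),
               image$voxel_size_mm)
}

#' Fully automatic E13.5 plexus segmentation
#'
#' Extends the primary mask to the whole plexus: (1) a local range image is
#' computed and thresholded at the mean range inside the primary mask; (2)
#' range components intersecting the primary mask are selected and closed;
#' (3) low-intensity voxels are removed from the selected region; (4) a
#' morphological opening sheds residual tissue and the largest connected
#' component is kept; (5) an active contour refines the result on the raw
#' image (the plexus is bright; set `ac_on_complement` to flip). If any step
#' empties the mask, the last nonempty stage is returned with a diagnostic.
#'
#' @param image a [volume_image].
#' @param primary nonempty primary [binary_mask] (from [primary_mask()]).
#' @param p a [plexus_params()].
#' @param sp a [segmentation_params()] (for the active-contour settings the
#'   two blocks share: iterations come from `p`).
#' @return A [binary_mask]; single 26-connected component on success, with
#'   attribute `diagnostic` naming the failing step otherwise.
#' @export
segment_e13 <- function(image, primary, p = plexus_params(),
                        sp = segmentation_params()) {
  stopifnot_same_geometry(image, primary, "image and primary mask")
  if (sum(primary$voxels) == 0L) stop("primary mask is empty")
  vs <- image$voxel_size_mm
  d <- dim(image$voxels)
  last <- primary
  fail <- function(step, mask) {
    warning("segment_e13: empty intermediate at step '", step,
            "'; returning the last nonempty stage")
    attr(mask, "diagnostic") <- step
    mask
  }

  rng <- local_range(image, p$range_window)
  thr <- mean(rng$voxels[primary$voxels])
  high_range <- binary_mask(rng$voxels > thr, vs)
  if (sum(high_range$voxels) == 0L) return(fail("range threshold", last))

  lab <- label_components(high_range, p$connectivity)
  touching <- unique(lab[primary$voxels])
  touching <- touching[touching > 0L]
  if (length(touching) == 0L) return(fail("component selection", last))
  sel <- binary_mask(array(lab %in% touching, d), vs)
  last <- sel

  closed <- mask_close(sel, p$closing_radius)
  if (sum(closed$voxels) == 0L) return(fail("closing", last))
  last <- closed

  thr2 <- high_threshold(image$voxels[closed$voxels], p)
  bright <- binary_mask(closed$voxels & image$voxels >= thr2, vs)
  if (sum(bright$voxels) == 0L) return(fail("low-intensity removal", last))
  last <- bright

  opened <- mask_open(bright, p$opening_radius)
  if (sum(opened$voxels) == 0L) return(fail("opening", last))
  largest <- keep_largest(opened, 1L, p$connectivity)
  last <- largest

  acp <- sp
  acp$ac_iterations <- p$ac_iterations
  acp$ac_smoothing <- p$ac_smoothing
  refined <- refine_active_contour(image, largest, acp,
                                   complement = p$ac_on_complement)
  if (sum(refined$voxels) == 0L) return(fail("active contour", last))
  keep_largest(refined, 1L, 26L)
}

#' Merge the automatic primary mask with manually segmented branches
#'
#' Voxelwise union; the lateral branches segmented externally for E15.5/E17.5
#' samples are added to the exported primary mask.
#'
#' @param primary,branches [binary_mask]s on the same grid.
#' @return The union [binary_mask] with attribute `added_voxels`.
#' @export
merge_manual <- function(primary, branches) {
  stopifnot_same_geometry(primary, branches, "primary and branch masks")
  out <- binary_mask(primary$voxels | branches$voxels, primary$voxel_size_mm)
  attr(out, "added_voxels") <- sum(out$voxels) - sum(primary$voxels)
  out
}

#' Run the full segmentation pipeline on one volume
#'
#' Preprocessing, ventricle localization (threshold, component separation,
#' ICP + Hausdorff selection against the reference mask, active-contour
#' refinement) and plexus extraction. For `stage = "E13.5"` the fully
#' automatic extension runs; for `"E15.5_17.5"` the pipeline stops after the
#' primary mask (optionally merging externally segmented branches). Every
#' stage is logged with its output volume and timing.
#'
#' @param image a [volume_image].
#' @param reference reference 4th-ventricle [binary_mask].
#' @param stage `"E13.5"` or `"E15.5_17.5"`.
#' @param sp a [segmentation_params()].
#' @param pp a [plexus_params()].
#' @param manual_branches optional [binary_mask] of manually segmented
#'   branches to merge (E15.5/E17.5 workflow).
#' @return A list of class `chopct_run`: `final`, `ventricle`, `primary`
#'   ([binary_mask]s) and `log` (one entry per executed stage).
#' @export
run_pipeline <- function(image, reference, stage = c("E13.5", "E15.5_17.5"),
                         sp = segmentation_params(), pp = plexus_params(),
                         manual_branches = NULL) {
  stage <- match.arg(stage)
  log <- list()
  note <- function(name, mask) {
    log[[length(log) + 1L]] <<- list(stage = name, voxels = sum(mask$voxels),
                                     time = Sys.time())
  }
  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  pre <- run("preprocess", preprocess(image, sp))
  log[[length(log) + 1L]] <- list(stage = "preprocess", voxels = NA_integer_,
                                  time = Sys.time())
  low <- run("threshold_low", threshold_low(pre, sp))
  note("threshold_low", low)
  cands <- run("separate_components", separate_components(low, sp))
  if (length(cands) == 0L) stop("pipeline stage 'separate_components' produced no components")
  log[[length(log) + 1L]] <- list(stage = "separate_components",
                                  voxels = sum(cands[[1L]]$voxels),
                                  n_components = length(cands), time = Sys.time())
  vent0 <- run("select_ventricle", select_ventricle(cands, reference, sp))
  note("select_ventricle", vent0)
  vent <- run("refine_active_contour", refine_active_contour(pre, vent0, sp))
  note("refine_active_contour", vent)
  prim <- run("primary_mask", primary_mask(pre, vent, pp))
  note("primary_mask", prim)

  final <- if (stage == "E13.5") {
    f <- run("segment_e13", segment_e13(pre, prim, pp, sp))
    note("segment_e13", f)
    f
  } else {
    prim
  }
  if (!is.null(manual_branches)) {
    final <- run("merge_manual", merge_manual(final, manual_branches))
    note("merge_manual", final)
  }
  structure(list(final = final, ventricle = vent, primary = prim,
                 stage = stage, log = log),
            class = "chopct_run")
}

#' @export
print.chopct_run <- function(x, ...) {
  cat(sprintf("<chopct_run> stage %s, %d stages, final mask %d voxels\n",
              x$stage, length(x$log), sum(x$final$voxels)))
  invisible(x)
}
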