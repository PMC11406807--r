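#' Read a micro-CT image stack
#'
#' Reads either a directory of per-slice TIFF files (stacked along the first
#' array axis in filename-sorted order, one slice per transverse plane) or a
#' single multi-page TIFF. Pixel data are promoted to double precision.
#'
#' @param path directory of `.tif`/`.tiff` slices, or one (multi-page) file.
#' @param voxel_size_mm voxel size override in mm; if `NULL` it is taken from
#'   the JSON payload this package writes into the ImageDescription tag, and
#'   an error is raised when neither source provides it.
#' @return A [volume_image].
#' @export
read_image_stack <- function(path, voxel_size_mm = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    pages <- list()
    for (f in files) {
      pg <- read_tiff_pages(f)
      if (length(pg) != 1L) stop("expected single-page slice files, got multi-page: ", f)
      pages[[length(pages) + 1L]] <- pg[[1L]]
      if (!identical(dim(pg[[1L]]$pixels), dim(pages[[1L]]$pixels))) {
        stop("slice shape mismatch in file ", f)
      }
    }
  } else if (file.exists(path)) {
    pages <- read_tiff_pages(path)
    shapes <- lapply(pages, function(p) dim(p$pixels))
    if (length(unique(shapes)) != 1L) stop("page shape mismatch in ", path)
  } else {
    stop("path does not exist: ", path)
  }
  if (is.null(voxel_size_mm)) voxel_size_mm <- description_voxel_size(pages)
  if (is.null(voxel_size_mm)) {
    stop("voxel size not found in TIFF metadata; pass voxel_size_mm explicitly")
  }
  sl <- dim(pages[[1L]]$pixels)
  vol <- array(0, c(length(pages), sl[1], sl[2]))
  for (k in seq_along(pages)) vol[k, , ] <- pages[[k]]$pixels
  volume_image(vol, voxel_size_mm)
}

description_voxel_size <- function(pages) {
  for (p in pages) {
    if (is.character(p$description) && nzchar(p$description)) {
      meta <- tryCatch(jsonlite::fromJSON(p$description), error = function(e) NULL)
      if (!is.null(meta$voxel_size_mm)) return(as.numeric(meta$voxel_size_mm))
    }
  }
  NULL
}

#' Write a volume or mask as a per-slice TIFF stack
#'
#' One file per transverse slice, named `slice_0001.tif`, `slice_0002.tif`,
#' ... Grayscale volumes are stored losslessly as 64-bit floats by default;
#' masks as 8-bit 0/255 (the encoding manual-segmentation tools expect). The
#' voxel size is embedded as JSON in the ImageDescription tag.
#'
#' @param v a [volume_image] or [binary_mask].
#' @param path output directory (created if missing).
#' @param dtype pixel type for grayscale volumes: `"float64"` (default,
#'   lossless), `"float32"`, `"uint16"` or `"uint8"`. Masks always use uint8.
#' @return Invisibly, the written file paths.
#' @export
write_image_stack <- function(v, path, dtype = "float64") {
  is_mask <- inherits(v, "binary_mask")
  if (!is_mask && !inherits(v, "volume_image")) {
    stop("v must be a volume_image or binary_mask")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$voxels)
  desc <- jsonlite::toJSON(list(voxel_size_mm = v$voxel_size_mm),
                           auto_unbox = TRUE, digits = NA)
  files <- character(d[1])
  for (k in seq_len(d[1])) {
    m <- v$voxels[k, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, d[2], d[3])
    if (is_mask) m <- matrix(as.numeric(m) * 255, d[2], d[3])
    files[k] <- file.path(path, sprintf("slice_%04d.tif", k))
    write_tiff_slice(m, files[k], dtype = if (is_mask) "uint8" else dtype,
                     description = as.character(desc))
  }
  invisible(files)
}

#' Read a binary mask stack
#'
#' Like [read_image_stack()] but thresholds pixel values at > 0 and returns a
#' [binary_mask] (masks are stored as 0/255).
#'
#' @inheritParams read_image_stack
#' @return A [binary_mask].
#' @export
read_mask_stack <- function(path, voxel_size_mm = NULL) {
  v <- read_image_stack(path, voxel_size_mm)
  binary_mask(v$voxels > 0, v$voxel_size_mm)
}

#' Triangulated surface of a binary mask
#'
#' Extracts the 0.5-level iso-surface of the mask indicator (marching
#' tetrahedra on a zero-padded copy, so surfaces close at the image border)
#' with vertices in mm (`index * voxel_size_mm`, coordinate order
#' `(z, y, x)`). The indicator is anti-aliased with a 3^3 box mean before
#' extraction, which removes the voxel staircase and brings the mesh area of
#' digitized solids within a few percent of the true surface; masks too thin
#' to survive the smoothing fall back to the raw binary field. For a single
#' solid component the mesh is watertight.
#'
#' @param mask a nonempty [binary_mask].
#' @param antialias smooth the indicator before extraction (default `TRUE`).
#' @return A list of class `surface_mesh`: `vertices` (n x 3, mm), `faces`
#'   (m x 3, 1-based vertex indices).
#' @export
mask_to_mesh <- function(mask, antialias = TRUE) {
  if (sum(mask$voxels) == 0L) stop("cannot mesh an empty mask")
  d <- dim(mask$voxels)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- as.numeric(mask$voxels)
  field <- if (antialias) box_mean3(pad) else pad
  mt <- cpp_marching_tetra(as.vector(field), dim(pad), 0.5)
  if (antialias && nrow(mt$faces) == 0L) {
    mt <- cpp_marching_tetra(as.vector(pad), dim(pad), 0.5)
  }
  verts <- (mt$vertices - 1) * mask$voxel_size_mm  # undo padding offset
  colnames(verts) <- c("z", "y", "x")
  structure(list(vertices = verts, faces = mt$faces), class = "surface_mesh")
}

# 3x3x3 box mean with clamped borders
box_mean3 <- function(a) {
  d <- dim(a)
  out <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    zi <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    yi <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    xi <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    out <- out + a[zi, yi, xi]
  }
  out / 27
}

#' Total surface area of a triangle mesh, in mm^2
#' @param mesh a `surface_mesh`.
#' @return Scalar area.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Export a mask surface as a binary STL file
#'
#' @param mask a nonempty [binary_mask].
#' @param path output `.stl` file.
#' @return Invisibly, the `surface_mesh` that was written.
#' @export
export_mesh_stl <- function(mask, path) {
  mesh <- mask_to_mesh(mask)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "chopct binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- c((p2[2] - p1[2]) * (p3[3] - p1[3]) - (p2[3] - p1[3]) * (p3[2] - p1[2]),
           (p2[3] - p1[3]) * (p3[1] - p1[1]) - (p2[1] - p1[1]) * (p3[3] - p1[3]),
           (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(mesh)
}

#' Read landmarks from a Slicer Markups fiducial file (.fcsv)
#'
#' Accepts the fiducial CSV dialect: `#`-prefixed header lines, then rows
#' `id,x,y,z,...,label,...`. Point order follows file order (it encodes
#' anatomical correspondence). A `# CoordinateSystem` header, when present, is
#' kept as the `coordinate_system` attribute; no axis conversion is applied.
#'
#' @param path an `.fcsv` file.
#' @return A [landmark_config()] (columns in file order x, y, z).
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no landmarks in ", path)
  pts <- matrix(NA_real_, length(body), 3)
  labels <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (length(f) < 4L || anyNA(xyz)) {
      stop(sprintf("malformed landmark row at line %d of %s",
                   which(lines == body[i])[1L], path))
    }
    pts[i, ] <- xyz
    labels[i] <- if (length(f) >= 12L) f[12L] else ""
  }
  if (nrow(pts) < 3L) {
    warning("fewer than 3 landmarks in ", path)
    cfg <- structure(list(points = pts, label = basename(path)),
                     class = "landmark_config")
  } else {
    cfg <- landmark_config(pts, label = basename(path))
  }
  cs <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs) > 0) {
    attr(cfg, "coordinate_system") <- trimws(sub(".*=", "", cs[[1L]]))
  }
  attr(cfg, "point_labels") <- labels
  cfg
}

#' Write landmarks to a Slicer Markups fiducial file (.fcsv)
#'
#' @param cfg a [landmark_config()].
#' @param path output file.
#' @param coordinate_system coordinate-system header value (default "LPS").
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(cfg, path, coordinate_system = "LPS") {
  lines <- c("# Markups fiducial file version = 4.11",
             paste0("# CoordinateSystem = ", coordinate_system),
             "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  labels <- attr(cfg, "point_labels")
  for (i in seq_len(nrow(cfg$points))) {
    lab <- if (!is.null(labels) && nzchar(labels[i])) labels[i] else sprintf("LM-%d", i)
    lines <- c(lines, sprintf("%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
                              i, cfg$points[i, 1], cfg$points[i, 2],
                              cfg$points[i, 3], lab))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write morphometry reports to CSV
#'
#' One row per sample, fixed column order with units in the header; `NaN`
#' fields are serialized as empty cells.
#'
#' @param reports a list of `morphometry_report` objects (see
#'   [build_report()]), possibly empty.
#' @param path output CSV file.
#' @return Invisibly, the data frame written.
#' @export
write_report <- function(reports, path) {
  cols <- c("sample", report_fields())
  if (length(reports) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$sample <- character(0)
  } else {
    rows <- lapply(reports, function(r) {
      vals <- lapply(report_fields(), function(f) {
        v <- r[[f]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      })
      c(list(sample = if (is.null(r$sample)) NA_character_ else r$sample),
        setNames(vals, report_fields()))
    })
    df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  }
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- ifelse(is.nan(df[[j]]), NA, df[[j]])
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(df)
}

report_fields <- function() {
  c("volume_mm3", "surface_area_mm2", "outgrowth_angle_deg",
    "ventricle_volume_mm3", "proportion", "rostral_volume_mm3",
    "caudal_volume_mm3", "left_length_mm", "right_length_mm",
    "left_angle_deg", "right_angle_deg", "central_length_mm",
    "total_length_mm", "ventricle_length_mm")
}
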