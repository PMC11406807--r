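# Minimal TIFF codec for uncompressed single-sample grayscale images.
#
# Scope: baseline TIFF, little- or big-endian, compression "none", one sample
# per pixel, 8/16-bit unsigned integer or 32/64-bit IEEE float, striped
# storage, optional multi-page files. That covers the per-slice stacks this
# pipeline exchanges with manual-segmentation tools; anything fancier is
# rejected with a clear message. Voxel size travels in the ImageDescription
# tag as a small JSON payload.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

read_u32 <- function(con, n = 1L, endian) {
  v <- readBin(con, "integer", n = n, size = 4L, endian = endian)
  ifelse(v < 0, v + 2^32, as.numeric(v))
}

read_tag_values <- function(raw_ifd, pos, con, endian) {
  # one 12-byte IFD entry starting at byte `pos` (1-based) of raw_ifd
  ent <- raw_ifd[pos:(pos + 11L)]
  tag <- readBin(ent[1:2], "integer", size = 2L, signed = FALSE, endian = endian)
  type <- readBin(ent[3:4], "integer", size = 2L, signed = FALSE, endian = endian)
  count <- readBin(ent[5:8], "integer", size = 4L, endian = endian)
  if (count < 0) count <- count + 2^32
  type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
  nbytes <- type_size * count
  payload <- if (nbytes <= 4L) {
    ent[9:(8L + nbytes)]
  } else {
    off <- readBin(ent[9:12], "integer", size = 4L, endian = endian)
    if (off < 0) off <- off + 2^32
    seek(con, off)
    readBin(con, "raw", n = nbytes)
  }
  values <- switch(as.character(type),
    "1" = as.numeric(readBin(payload, "integer", n = count, size = 1L,
                             signed = FALSE, endian = endian)),
    "2" = rawToChar(payload[payload != as.raw(0)]),
    "3" = as.numeric(readBin(payload, "integer", n = count, size = 2L,
                             signed = FALSE, endian = endian)),
    "4" = {
      v <- readBin(payload, "integer", n = count, size = 4L, endian = endian)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "11" = readBin(payload, "double", n = count, size = 4L, endian = endian),
    "12" = readBin(payload, "double", n = count, size = 8L, endian = endian),
    NULL)
  list(tag = tag, values = values)
}

read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file: ", path)
  forty_two <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
  if (forty_two != 42L) stop("bad TIFF magic number in ", path)
  ifd_off <- read_u32(con, 1L, endian)

  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_entries <- readBin(con, "integer", size = 2L, signed = FALSE, endian = endian)
    raw_ifd <- readBin(con, "raw", n = 12L * n_entries)
    next_off <- read_u32(con, 1L, endian)

    tags <- list()
    for (e in seq_len(n_entries)) {
      tv <- read_tag_values(raw_ifd, 12L * (e - 1L) + 1L, con, endian)
      if (!is.null(tv$values)) tags[[as.character(tv$tag)]] <- tv$values
    }
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[id]])]]
      if (is.null(v)) default else v
    }
    width <- gt("width"); height <- gt("length")
    if (is.null(width) || is.null(height)) stop("TIFF missing dimensions: ", path)
    if (gt("compression", 1) != 1) stop("compressed TIFF not supported: ", path)
    if (gt("samples_per_pixel", 1) != 1) stop("multi-sample TIFF not supported: ", path)
    bits <- gt("bits", 1)
    fmt <- gt("sample_format", 1)
    offs <- gt("strip_offsets"); cnts <- gt("strip_byte_counts")
    if (is.null(offs)) stop("TIFF missing strip offsets: ", path)
    if (is.null(cnts)) cnts <- rep(width * height * bits / 8 / length(offs), length(offs))

    buf <- raw(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      buf <- c(buf, readBin(con, "raw", n = cnts[s]))
    }
    px <- if (fmt == 3 && bits == 64) {
      readBin(buf, "double", n = width * height, size = 8L, endian = endian)
    } else if (fmt == 3 && bits == 32) {
      readBin(buf, "double", n = width * height, size = 4L, endian = endian)
    } else if (fmt %in% c(1, 4) && bits == 16) {
      as.numeric(readBin(buf, "integer", n = width * height, size = 2L,
                         signed = FALSE, endian = endian))
    } else if (fmt %in% c(1, 4) && bits == 8) {
      as.numeric(readBin(buf, "integer", n = width * height, size = 1L,
                         signed = FALSE, endian = endian))
    } else {
      stop(sprintf("unsupported TIFF pixel type (bits=%d, format=%d): %s",
                   bits, fmt, path))
    }
    # data are row-major; build the (rows x cols) matrix
    m <- matrix(px, nrow = width, ncol = height)
    pages[[length(pages) + 1L]] <- list(pixels = t(m), description = gt("description"))
    ifd_off <- next_off
  }
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  pages
}

write_tiff_slice <- function(m, path, dtype, description = NULL) {
  height <- nrow(m); width <- ncol(m)
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L, float64 = 64L,
                 stop("unsupported dtype: ", dtype))
  fmt <- if (dtype %in% c("uint8", "uint16")) 1L else 3L
  nbytes <- width * height * bits / 8L
  desc <- if (is.null(description)) raw(0) else c(charToRaw(description), as.raw(0))
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0))

  data_off <- 8L
  desc_off <- data_off + nbytes
  if (desc_off %% 2L == 1L) desc_off <- desc_off + 1L
  ifd_off <- desc_off + length(desc)

  tags <- list(
    c(TIFF_TAGS[["width"]], 4L, 1L, width),
    c(TIFF_TAGS[["length"]], 4L, 1L, height),
    c(TIFF_TAGS[["bits"]], 3L, 1L, bits),
    c(TIFF_TAGS[["compression"]], 3L, 1L, 1L),
    c(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
  )
  if (length(desc) > 0L) {
    tags <- c(tags, list(c(TIFF_TAGS[["description"]], 2L, length(desc), desc_off)))
  }
  tags <- c(tags, list(
    c(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off),
    c(TIFF_TAGS[["samples_per_pixel"]], 3L, 1L, 1L),
    c(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, height),
    c(TIFF_TAGS[["strip_byte_counts"]], 4L, 1L, nbytes),
    c(TIFF_TAGS[["sample_format"]], 3L, 1L, fmt)
  ))
  tags <- tags[order(vapply(tags, `[`, 0, 1L))]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4L, endian = "little")

  px <- as.vector(t(m))  # row-major
  if (dtype == "uint8") {
    writeBin(as.raw(pmin(pmax(round(px), 0), 255)), con)
  } else if (dtype == "uint16") {
    suppressWarnings(writeBin(as.integer(pmin(pmax(round(px), 0), 65535)), con,
                              size = 2L, endian = "little"))
  } else if (dtype == "float32") {
    writeBin(as.numeric(px), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(px), con, size = 8L, endian = "little")
  }
  if (desc_off > data_off + nbytes) writeBin(as.raw(0), con)
  if (length(desc) > 0L) writeBin(desc, con)

  writeBin(as.integer(length(tags)), con, size = 2L, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2L, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2L, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4L, endian = "little")
    if (tg[2] == 3L) {  # SHORT: value left-justified in the 4-byte slot
      writeBin(as.integer(tg[4]), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4L, endian = "little")
    }
  }
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}
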