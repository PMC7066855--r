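#' Construct a volumetric image stack
#'
#' An `image_stack` holds a 3D intensity volume with anisotropic physical
#' voxel spacing. Axis order is (z, y, x): `voxels[iz, iy, ix]`. Spacing and
#' origin are in micrometres; voxel index i (1-based) has its physical
#' centre at `(i - 0.5) * spacing + origin`.
#'
#' @param voxels numeric 3D array with dim (nz, ny, nx)
#' @param spacing numeric length-3, (dz, dy, dx) in um, all > 0
#' @param origin numeric length-3, (z0, y0, x0) in um
#' @return an object of class `image_stack`
#' @export
image_stack <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive values (dz, dy, dx)")
  if (any(dim(voxels) < 1L)) stopf("all stack dimensions must be >= 1")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal baseline TIFF codec (uncompressed, single-sample grayscale,
# 8/16-bit unsigned or 32-bit IEEE float, one strip per page). No suitable
# TIFF package is available in the target library set, and the subset of the
# format needed for CLSM stack interchange is small enough to implement
# directly against the TIFF 6.0 baseline.
# ---------------------------------------------------------------------------

tiff_write_pages <- function(pages, path, format) {
  bits <- switch(format, uint8 = 8L, uint16 = 16L, float32 = 32L,
                 stopf("unsupported TIFF format '%s'", format))
  sample_format <- if (format == "float32") 3L else 1L
  bytes_per <- bits / 8L
  height <- nrow(pages[[1]]); width <- ncol(pages[[1]])
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  if (ifd_size %% 2L == 1L) ifd_size <- ifd_size + 1L
  page_bytes <- width * height * bytes_per
  if (page_bytes %% 2L == 1L) page_bytes_padded <- page_bytes + 1L else page_bytes_padded <- page_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(ifelse(x > 32767, x - 65536, x)),
                              con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header: little-endian, magic 42, first IFD right after the header
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(8L)

  offset <- 8
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    if (nrow(m) != height || ncol(m) != width)
      stopf("all pages must share the same dimensions")
    data_offset <- offset + ifd_size
    next_ifd <- if (p < length(pages)) data_offset + page_bytes_padded else 0
    # IFD: tag count, then tags sorted by code, then next-IFD offset
    w16(n_tags)
    tag <- function(code, type, count, value) {
      w16(code); w16(type); w32(count)
      if (type == 3L) { w16(value); w16(0L) } else w32(value)
    }
    tag(256L, 4L, 1L, width)          # ImageWidth
    tag(257L, 4L, 1L, height)         # ImageLength
    tag(258L, 3L, 1L, bits)           # BitsPerSample
    tag(259L, 3L, 1L, 1L)             # Compression: none
    tag(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_offset)    # StripOffsets
    tag(277L, 3L, 1L, 1L)             # SamplesPerPixel
    tag(278L, 4L, 1L, height)         # RowsPerStrip: one strip per page
    tag(279L, 4L, 1L, page_bytes)     # StripByteCounts
    tag(339L, 3L, 1L, sample_format)  # SampleFormat
    w32(next_ifd)
    if (ifd_size > 2L + n_tags * 12L + 4L) writeBin(as.raw(0L), con)
    # pixel data, row-major (scanlines are image rows)
    v <- as.vector(t(m))
    if (format == "float32") {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    } else if (format == "uint16") {
      if (any(v < 0 | v > 65535)) stopf("uint16 TIFF requires values in [0, 65535]")
      w16(round(v))
    } else {
      if (any(v < 0 | v > 255)) stopf("uint8 TIFF requires values in [0, 255]")
      writeBin(as.raw(round(v)), con)
    }
    if (page_bytes_padded > page_bytes) writeBin(as.raw(0L), con)
    offset <- data_offset + page_bytes_padded
  }
  invisible(path)
}

tiff_read_pages <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, "raw", 2L))
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stopf("not a TIFF file (bad byte-order mark): %s", path))
  r16 <- function(n = 1L) readBin(con, "integer", n, size = 2L, endian = endian, signed = FALSE)
  r32 <- function(n = 1L) readBin(con, "integer", n, size = 4L, endian = endian)
  if (r16() != 42L) stopf("not a TIFF file (bad magic number): %s", path)
  ifd_offset <- r32()

  pages <- list()
  while (ifd_offset != 0L) {
    seek(con, ifd_offset)
    n_tags <- r16()
    tags <- vector("list", n_tags)
    for (i in seq_len(n_tags)) {
      code <- r16(); type <- r16(); count <- r32()
      value_raw <- readBin(con, "raw", 4L)
      tags[[i]] <- list(code = code, type = type, count = count, raw = value_raw)
    }
    next_ifd <- r32()

    tag_value <- function(code, default = NULL) {
      hit <- Filter(function(t) t$code == code, tags)
      if (length(hit) == 0L) return(default)
      t <- hit[[1]]
      bytes_per <- switch(as.character(t$type), `1` = 1L, `3` = 2L, `4` = 4L,
                          stopf("unsupported TIFF tag type %d (tag %d)", t$type, code))
      inline <- t$count * bytes_per <= 4L
      decode <- function(src, n) {
        if (t$type == 3L) readBin(src, "integer", n, size = 2L, endian = endian, signed = FALSE)
        else if (t$type == 4L) readBin(src, "integer", n, size = 4L, endian = endian)
        else as.integer(readBin(src, "raw", n))
      }
      if (inline) {
        decode(t$raw, t$count)
      } else {
        off <- readBin(t$raw, "integer", 1L, size = 4L, endian = endian)
        seek(con, off)
        decode(con, t$count)
      }
    }

    width <- tag_value(256L); height <- tag_value(257L)
    bits <- tag_value(258L, 8L)[1]
    compression <- tag_value(259L, 1L)
    strip_offsets <- tag_value(273L)
    rows_per_strip <- tag_value(278L, height)[1]
    strip_counts <- tag_value(279L)
    sample_format <- tag_value(339L, 1L)[1]
    samples_per_pixel <- tag_value(277L, 1L)[1]

    if (is.null(width) || is.null(height) || is.null(strip_offsets))
      stopf("TIFF page missing required tags")
    if (compression != 1L) stopf("only uncompressed TIFF is supported")
    if (samples_per_pixel != 1L) stopf("only single-sample (grayscale) TIFF is supported")
    if (!(bits %in% c(8L, 16L, 32L))) stopf("unsupported bit depth: %d", bits)
    if (bits == 32L && sample_format != 3L) stopf("32-bit TIFF must be IEEE float")
    if (is.null(strip_counts)) strip_counts <- rep(width * rows_per_strip * bits / 8L,
                                                   length(strip_offsets))

    n_px <- width * height
    values <- numeric(0)
    for (s in seq_along(strip_offsets)) {
      seek(con, strip_offsets[s])
      n_vals <- strip_counts[s] / (bits / 8L)
      v <- if (bits == 32L) readBin(con, "numeric", n_vals, size = 4L, endian = endian)
           else if (bits == 16L) readBin(con, "integer", n_vals, size = 2L, endian = endian, signed = FALSE)
           else as.integer(readBin(con, "raw", n_vals))
      values <- c(values, v)
    }
    if (length(values) != n_px) stopf("TIFF strip data does not match page size")
    pages[[length(pages) + 1L]] <- matrix(values, nrow = height, ncol = width, byrow = TRUE)
    ifd_offset <- next_ifd
  }
  if (length(pages) == 0L) stopf("TIFF file contains no pages")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("TIFF pages have unequal dimensions; refusing to crop")
  pages
}

#' Write an image stack to a multi-page TIFF
#'
#' Each z-slice becomes one TIFF page (grayscale, uncompressed). Intensities
#' are written without rescaling.
#'
#' @param stack an [image_stack()]
#' @param path output file path
#' @param format one of "float32" (default for non-integer data), "uint16",
#'   "uint8"
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, format = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  if (is.null(format)) {
    is_int <- all(v == round(v)) && min(v) >= 0
    format <- if (!is_int) "float32" else if (max(v) <= 65535) "uint16" else "float32"
  }
  nz <- dim(v)[1]
  pages <- lapply(seq_len(nz), function(iz) v[iz, , , drop = TRUE])
  if (nz == 1L) pages <- list(matrix(v[1, , ], dim(v)[2], dim(v)[3]))
  tiff_write_pages(pages, path, format)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Page i becomes z-slice i; intensities are preserved without rescaling.
#' Physical spacing is not stored in baseline TIFF tags, so the caller must
#' supply it.
#'
#' @param path TIFF file path
#' @param spacing numeric length-3 (dz, dy, dx) in um
#' @param origin numeric length-3 (z0, y0, x0) in um
#' @return an [image_stack()]
#' @export
read_stack <- function(path, spacing, origin = c(0, 0, 0)) {
  pages <- tiff_read_pages(path)
  nz <- length(pages); ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  voxels <- array(0, dim = c(nz, ny, nx))
  for (iz in seq_len(nz)) voxels[iz, , ] <- pages[[iz]]
  image_stack(voxels, spacing = spacing, origin = origin)
}

# ---------------------------------------------------------------------------
# Well plate maps
# ---------------------------------------------------------------------------

#' Construct a 96-well plate map
#'
#' Holds an 8 x 12 matrix of well values: logical occupancy (captured or
#' not) or fractional success rates in [0, 1]. Rows are labelled A-H top to
#' bottom, columns 1-12 left to right, matching the standard plate layout
#' with A1 at top-left.
#'
#' @param values 8 x 12 matrix, logical or numeric in [0, 1]
#' @return an object of class `well_plate_map`
#' @export
plate_map <- function(values) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(8L, 12L))) stopf("plate map must be exactly 8 x 12")
  if (is.logical(values)) values <- values * 1.0
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stopf("plate map values must be fractions in [0, 1]")
  dimnames(values) <- list(LETTERS[1:8], as.character(1:12))
  structure(list(values = values), class = "well_plate_map")
}

#' @export
print.well_plate_map <- function(x, ...) {
  cat("well_plate_map (8 x 12):\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Read a plate map from CSV
#'
#' Expects a header row with columns 1-12 and a leading label column with
#' rows A-H in order. Values 0/1 are accepted as boolean occupancy;
#' fractions in [0, 1] are accepted for averaged maps.
#'
#' @param path CSV file path
#' @return a [plate_map()]
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 13L) stopf("plate map CSV must have a row-label column plus columns 1-12")
  labels <- as.character(df[[1]])
  if (nrow(df) != 8L || !identical(labels, LETTERS[1:8]))
    stopf("plate map CSV must have rows A-H in order (got: %s)",
          paste(labels, collapse = ","))
  if (!identical(names(df)[-1], as.character(1:12)))
    stopf("plate map CSV must have column headers 1-12 in order")
  m <- as.matrix(df[, -1])
  if (!is.numeric(m)) stopf("plate map values must be numeric")
  plate_map(m)
}

#' Write a plate map to CSV
#'
#' @param map a [plate_map()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_plate_map <- function(map, path) {
  stopifnot(inherits(map, "well_plate_map"))
  df <- data.frame(row = LETTERS[1:8], map$values, check.names = FALSE)
  names(df) <- c("row", as.character(1:12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
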