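# Image and annotation I/O: PNG/JPEG via the png/jpeg packages, plus a
# deliberately minimal reader for single-frame, uncompressed,
# little-endian CT DICOM (no DICOM package is available as a dependency;
# the subset implemented covers monochrome CT slices only).

#' Write an 8-bit image array as PNG
#'
#' @param image (H, W) matrix or (H, W, 3) array of integers in 0-255.
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  img <- image / 255
  ok <- try(png::writePNG(img, target = path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stopf("failed to write PNG '%s': %s", path, attr(ok, "condition")$message)
  invisible(path)
}

#' Write a binary mask as PNG
#'
#' @param mask (H, W) matrix with values in \{0, 1\}.
#' @param path output path.
#' @param values `"0-255"` stores foreground as 255; `"0-1"` stores it as 1.
#' @export
write_mask_png <- function(mask, path, values = c("0-255", "0-1")) {
  values <- match.arg(values)
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary {0,1}")
  scale <- if (values == "0-255") 255 else 1
  write_image_png(mask * scale, path)
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("jpg", "jpeg")) return("jpg")
  if (ext %in% c("dcm", "dicom", "ima")) return("dicom")
  # magic-byte fallback
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  if (length(hdr) >= 8 && identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))))
    return("png")
  if (length(hdr) >= 2 && identical(hdr[1:2], as.raw(c(0xFF, 0xD8))))
    return("jpg")
  if (length(hdr) >= 132 && rawToChar(hdr[129:132]) == "DICM")
    return("dicom")
  stopf("unsupported or unreadable image format: '%s'", path)
}

# convert a png/jpeg array ([0,1] doubles, possibly multi-channel) to an
# 8-bit (H, W) or (H, W, 3) integer array
to_uint8 <- function(arr) {
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    arr <- arr[, , seq_len(min(3L, nc)), drop = FALSE]  # drop alpha
    if (dim(arr)[3] == 1L) arr <- arr[, , 1]
  }
  round(arr * 255)
}

#' Load a CT-like slice into the canonical representation
#'
#' Reads PNG, JPEG or single-frame DICOM, converts to 8-bit, replicates
#' grayscale to three identical channels, and resizes to `target_size`
#' (bilinear).  DICOM pixel data are windowed to 8-bit by per-slice min-max
#' scaling by default, or by a fixed window such as the lung window
#' `c(-1000, 400)` given in rescaled (HU) units.
#'
#' @param path image path.
#' @param target_size side length after conversion, or `NULL` to keep the
#'   native size.
#' @param window optional `c(low, high)` intensity window for DICOM input.
#' @return An object of class `slice_record` with fields `image`
#'   ((S, S, 3) integer array in 0-255), `source_path` and `format_tag`.
#' @export
load_slice <- function(path, target_size = NULL, window = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  fmt <- detect_format(path)
  img <- switch(fmt,
    png = to_uint8(png::readPNG(path)),
    jpg = to_uint8(jpeg::readJPEG(path)),
    dicom = read_dicom_image(path, window = window))
  if (is.matrix(img)) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (length(dim(img)) == 3 && dim(img)[3] == 2L) {
    img <- array(rep(img[, , 1], 3L), dim = c(dim(img)[1:2], 3L))
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h != w)
    warning(sprintf("non-square input %dx%d in '%s'; resizing to square", h, w,
                    basename(path)))
  if (!is.null(target_size) || h != w) {
    s <- if (is.null(target_size)) max(h, w) else as.integer(target_size)
    if (h != s || w != s) {
      out <- array(0, dim = c(s, s, 3L))
      for (ch in 1:3) out[, , ch] <- resize_bilinear(img[, , ch], s, s)
      img <- round(out)
    }
  }
  structure(list(image = array(as.integer(img), dim = dim(img)),
                 source_path = path, format_tag = fmt),
            class = "slice_record")
}

#' Load a ground-truth mask PNG
#'
#' Accepts the \{0, 1\} and \{0, 255\} dialects and returns a canonical
#' \{0, 1\} integer matrix.
#'
#' @param path mask path.
#' @param expected_dim optional `c(H, W)`; a mismatch raises an error.
#' @export
load_mask <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  arr <- to_uint8(png::readPNG(path))
  m <- if (is.matrix(arr)) arr else arr[, , 1]
  vals <- sort(unique(as.vector(m)))
  if (length(vals) > 2)
    stopf("mask '%s' has more than 2 distinct values: %s", path,
          paste(utils::head(vals, 10), collapse = ", "))
  if (!all(vals %in% c(0, 1, 255)))
    stopf("mask '%s' has unsupported values: %s", path,
          paste(vals, collapse = ", "))
  m[m == 255] <- 1L
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (!is.null(expected_dim) && !all(dim(m) == expected_dim[1:2]))
    stopf("mask '%s' is %dx%d but expected %dx%d", path, nrow(m), ncol(m),
          expected_dim[1], expected_dim[2])
  m
}

# ---------------------------------------------------------------------------
# Minimal DICOM support (single-frame, uncompressed, little endian)

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
read_u32 <- function(raw, off) {
  as.numeric(raw[off + 1]) + 256 * as.numeric(raw[off + 2]) +
    65536 * as.numeric(raw[off + 3]) + 16777216 * as.numeric(raw[off + 4])
}

# Parse enough of a DICOM file to recover the pixel matrix of a single
# monochrome frame.  Supported transfer syntaxes: explicit and implicit VR
# little endian, uncompressed.  Anything else raises a format error.
read_dicom_raster <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "raw", sz)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stopf("'%s' is not a DICOM part-10 file (missing DICM magic)", path)
  off <- 132L  # 0-based offset just past the magic
  meta <- list(rows = NA, cols = NA, bits = 16L, signed = FALSE,
               slope = 1, intercept = 0, ts = "1.2.840.10008.1.2.1")
  explicit <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pixel <- NULL
  while (off + 8 <= length(raw)) {
    group <- read_u16(raw, off); elem <- read_u16(raw, off + 2)
    in_meta <- group == 2L
    is_explicit <- in_meta || explicit
    if (is_explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% long_vrs) {
        len <- read_u32(raw, off + 8); hdr <- 12L
      } else {
        len <- read_u16(raw, off + 6); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- read_u32(raw, off + 4); hdr <- 8L
    }
    if (len == 4294967295) stopf("undefined-length element in '%s' (compressed pixel data is not supported)", path)
    val_off <- off + hdr
    if (val_off + len > length(raw)) stopf("truncated DICOM file '%s'", path)
    val <- raw[(val_off + 1):(val_off + len)]
    key <- sprintf("%04x%04x", group, elem)
    if (key == "00020010") {
      ts <- sub("\\s+$", "", rawToChar(val[val != as.raw(0)]))
      meta$ts <- ts
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stopf("unsupported DICOM transfer syntax '%s' in '%s'", ts, path)
    } else if (key == "00280010") meta$rows <- read_u16(val, 0)
    else if (key == "00280011") meta$cols <- read_u16(val, 0)
    else if (key == "00280100") meta$bits <- read_u16(val, 0)
    else if (key == "00280103") meta$signed <- read_u16(val, 0) == 1L
    else if (key == "00281052") meta$intercept <- as.numeric(rawToChar(val))
    else if (key == "00281053") meta$slope <- as.numeric(rawToChar(val))
    else if (key == "7fe00010") { pixel <- val; break }
    off <- val_off + len
  }
  if (is.null(pixel) || is.na(meta$rows) || is.na(meta$cols))
    stopf("no pixel data found in DICOM file '%s'", path)
  n <- meta$rows * meta$cols
  if (meta$bits == 8) {
    v <- as.integer(pixel[seq_len(n)])
  } else if (meta$bits == 16) {
    v <- readBin(pixel, what = "integer", n = n, size = 2L,
                 signed = meta$signed, endian = "little")
  } else stopf("unsupported BitsAllocated=%d in '%s'", meta$bits, path)
  v <- v * meta$slope + meta$intercept
  # DICOM pixel data is row-major (raster order); R matrices are column-major
  m <- matrix(v, nrow = meta$rows, ncol = meta$cols, byrow = TRUE)
  list(matrix = m, meta = meta)
}

# Window a DICOM raster to 8-bit.  Default is per-slice min-max; a fixed
# `window = c(low, high)` clips then scales (degenerate windows map to 0).
read_dicom_image <- function(path, window = NULL) {
  d <- read_dicom_raster(path)
  m <- d$matrix
  if (is.null(window)) {
    lo <- min(m); hi <- max(m)
  } else {
    lo <- window[1]; hi <- window[2]
    m <- clamp(m, lo, hi)
  }
  if (hi <= lo) return(matrix(0L, nrow(m), ncol(m)))
  round((m - lo) / (hi - lo) * 255)
}

# Write a tiny synthetic single-frame DICOM file (explicit VR little
# endian).  Exists so that the DICOM reader can be exercised without any
# third-party imaging data; not a general-purpose writer.
write_synthetic_dicom <- function(m, path, slope = 1, intercept = 0) {
  stopifnot(is.matrix(m))
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  elem_short <- function(group, el, vr, val) {
    c(u16(group), u16(el), charToRaw(vr), u16(length(val)), val)
  }
  elem_long <- function(group, el, vr, val) {
    c(u16(group), u16(el), charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(val), raw(), size = 4L, endian = "little"), val)
  }
  pad_even <- function(s) { if (nchar(s) %% 2 == 1) paste0(s, " ") else s }
  ts_raw <- charToRaw("1.2.840.10008.1.2.1")
  if (length(ts_raw) %% 2 == 1) ts_raw <- c(ts_raw, as.raw(0))
  meta_body <- elem_short(0x0002, 0x0010, "UI", ts_raw)
  body <- c(
    elem_short(0x0008, 0x0060, "CS", charToRaw("CT")),
    elem_short(0x0028, 0x0010, "US", u16(nrow(m))),
    elem_short(0x0028, 0x0011, "US", u16(ncol(m))),
    elem_short(0x0028, 0x0100, "US", u16(16L)),
    elem_short(0x0028, 0x0103, "US", u16(1L)),  # signed
    elem_short(0x0028, 0x1052, "DS", charToRaw(pad_even(format(intercept)))),
    elem_short(0x0028, 0x1053, "DS", charToRaw(pad_even(format(slope))))
  )
  pix <- writeBin(as.integer(t(m)), raw(), size = 2L, endian = "little")
  body <- c(body, elem_long(0x7FE0, 0x0010, "OW", pix))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  # file meta group length element
  writeBin(c(u16(0x0002), u16(0x0000), charToRaw("UL"), u16(4L),
             writeBin(length(meta_body), raw(), size = 4L, endian = "little"),
             meta_body, body), con)
  invisible(path)
}
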