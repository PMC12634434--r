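# Minimal baseline TIFF codec (uncompressed, little-endian, grayscale,
# multi-page). No TIFF package exists in this toolchain, so the subset of
# the format the package needs -- integer z-stacks, one page per z-plane --
# is read and written directly. Not a general-purpose TIFF reader.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_counts = 279L, sample_format = 339L)

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Uncompressed little-endian baseline TIFF, one page per z-plane, unsigned
#' 8/16/32-bit samples. Intensities are rounded and clamped to the sample
#' range. Pages store rows along y, so arrays round-trip exactly through
#' [read_tiff()].
#'
#' @param stack An [image_stack()] or a 3D array (x, y, z).
#' @param path Output path.
#' @param bits Bits per sample: 8, 16 (default) or 32.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path, bits = 16L) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (inherits(stack, "label_volume")) vox <- stack$labels
  if (length(dim(vox)) != 3) abort("need a 3D array")
  if (!bits %in% c(8L, 16L, 32L)) abort("`bits` must be 8, 16 or 32")
  maxval <- 2^bits - 1
  d <- dim(vox)
  con <- file(path, "wb")
  on.exit(close(con))

  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset: header(8) + all pixel data
  bytes_pp <- bits / 8
  page_bytes <- d[1] * d[2] * bytes_pp
  ifd0 <- 8 + page_bytes * d[3]
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")

  # pixel data, page-major, row-major within a page (rows = y)
  for (k in seq_len(d[3])) {
    plane <- pmin(pmax(round(vox[, , k]), 0), maxval)
    # R arrays are column-major in x; transpose so x varies fastest per row
    v <- as.vector(plane)  # x fastest, then y == row-major rows of y? no:
    # plane[x, y]: as.vector runs x fastest within y -- exactly row y's pixels
    if (bits == 32L) {
      # writeBin has no unsigned 32-bit; values above 2^31-1 are not expected
      writeBin(as.integer(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(v), con, size = bytes_pp, endian = "little")
    }
  }

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4
  for (k in seq_len(d[3])) {
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(TIFF_TAGS["width"], 3L, 1L, d[1])
    entry(TIFF_TAGS["length"], 3L, 1L, d[2])
    entry(TIFF_TAGS["bits"], 3L, 1L, bits)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, 8 + (k - 1) * page_bytes)
    entry(TIFF_TAGS["rows_per_strip"], 3L, 1L, d[2])
    entry(TIFF_TAGS["strip_counts"], 4L, 1L, page_bytes)
    entry(TIFF_TAGS["sample_format"], 3L, 1L, 1L)
    next_ifd <- if (k < d[3]) ifd0 + k * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a 3D array
#'
#' Supports the subset written by [write_tiff()]: uncompressed little-endian
#' grayscale, 8/16/32 bits per sample, one or more strips per page.
#'
#' @param path TIFF file path.
#' @param voxel_size Optional `(dx, dy, dz)`; when given, an
#'   [image_stack()] is returned instead of a bare array.
#' @param channel Channel label for the returned stack.
#' @return 3D array `(x, y, z)`, or an [image_stack()] when `voxel_size` is
#'   supplied.
#' @export
read_tiff <- function(path, voxel_size = NULL, channel = "ALL") {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42) {
    abort("not a little-endian TIFF file")
  }
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- u16(base)
      type <- u16(base + 2)
      count <- u32(base + 4)
      # inline value for the sizes used here (SHORT/LONG, count small)
      val <- if (type == 3 && count == 1) u16(base + 8)
      else if (count == 1) u32(base + 8)
      else {
        off <- u32(base + 8)
        step <- if (type == 3) 2 else 4
        vapply(seq_len(count) - 1, function(i) {
          if (type == 3) u16(off + i * step) else u32(off + i * step)
        }, numeric(1))
      }
      tags[[as.character(tag)]] <- val
    }
    get_tag <- function(id, default = NULL) {
      tags[[as.character(id)]] %||% default
    }
    if (get_tag(259L, 1) != 1) abort("only uncompressed TIFF is supported")
    w <- get_tag(256L); h <- get_tag(257L)
    bits <- get_tag(258L, 1)
    offs <- get_tag(273L); cnts <- get_tag(279L)
    if (is.null(w) || is.null(h) || is.null(offs)) abort("malformed TIFF IFD")
    bytes_pp <- bits / 8
    buf <- raw(0)
    for (s in seq_along(offs)) {
      buf <- c(buf, raw[offs[s] + seq_len(cnts[s])])
    }
    v <- readBin(buf, "integer", n = w * h, size = bytes_pp,
                 signed = bits == 32, endian = "little")
    if (bits < 32) v <- bitwAnd(v, as.integer(2^bits - 1))
    pages[[length(pages) + 1L]] <- matrix(v, nrow = w, ncol = h)
    ifd_off <- u32(ifd_off + 2 + n * 12)
  }
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (is.null(voxel_size)) arr else image_stack(arr, voxel_size, channel = channel)
}
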