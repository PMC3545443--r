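# Minimal baseline TIFF codec for grayscale stacks.
#
# No TIFF reader/writer is available in the supported dependency set,
# so flygait ships a small self-contained codec restricted to the
# subset of baseline TIFF it writes itself and that scientific cameras
# commonly emit: uncompressed, single-sample (grayscale), 8- or
# 16-bit, strip-organized, little- or big-endian, single- or
# multi-page.  Anything else (compression, tiles, RGB, palettes) is
# rejected with a clear error rather than mis-read.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

rd_uint <- function(raw, pos, size, endian) {
  b <- as.integer(raw[pos:(pos + size - 1L)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1L))
}

#' Write a grayscale matrix (or list of matrices) as a TIFF file
#'
#' Intensities in `[0, 1]` are quantized to unsigned 16-bit (default)
#' or 8-bit samples and stored uncompressed, one strip per page,
#' little-endian.  A list of matrices produces a multi-page file.
#'
#' @param image numeric matrix with values in `[0, 1]`, or a list of
#'   such matrices (all the same shape) for a multi-page file.
#' @param path output file path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, bits = 16L) {
  if (is.matrix(image)) image <- list(image)
  if (!length(image) || !all(vapply(image, is.matrix, TRUE)))
    stop_fg("'image' must be a matrix or a non-empty list of matrices")
  if (!bits %in% c(8L, 16L)) stop_fg("'bits' must be 8 or 16")
  dims <- unique(lapply(image, dim))
  if (length(dims) != 1L) stop_fg("all pages must share one shape")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  maxv <- 2^bits - 1

  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }

  n_bytes <- w * h * (bits / 8L)
  ifd_size <- 2L + 10L * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  # layout per page: pixel data first, then its IFD
  writeBin(charToRaw("II"), con); u16(42L); u32(8L + n_bytes)
  offset <- 8L
  for (p in seq_along(image)) {
    v <- round(pmin(pmax(image[[p]], 0), 1) * maxv)
    v <- as.vector(t(v))                      # scanline (row) major
    if (bits == 16L) {
      raw_px <- as.raw(rbind(v %% 256, v %/% 256))
    } else {
      raw_px <- as.raw(v)
    }
    writeBin(raw_px, con)
    ifd_off <- offset + n_bytes
    u16(10L)
    entry(256L, 4L, 1L, w)                    # ImageWidth
    entry(257L, 4L, 1L, h)                    # ImageLength
    entry(258L, 3L, 1L, bits)                 # BitsPerSample
    entry(259L, 3L, 1L, 1L)                   # Compression: none
    entry(262L, 3L, 1L, 1L)                   # Photometric: BlackIsZero
    entry(273L, 4L, 1L, offset)               # StripOffsets
    entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    entry(278L, 4L, 1L, h)                    # RowsPerStrip
    entry(279L, 4L, 1L, n_bytes)              # StripByteCounts
    entry(339L, 3L, 1L, 1L)                   # SampleFormat: uint
    offset <- ifd_off + ifd_size               # next page's pixel data
    u32(if (p < length(image)) offset + n_bytes else 0L)
  }
  invisible(path)
}

#' Read a grayscale TIFF file
#'
#' Reads uncompressed strip-organized grayscale baseline TIFF (8- or
#' 16-bit, either byte order, one or many pages).  Intensities are
#' normalized to `[0, 1]`.
#'
#' @param path file path.
#' @return a matrix for a single-page file, otherwise a list of
#'   matrices (one per page).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop_fg("'%s' is not a TIFF file", path)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop_fg("'%s' is not a TIFF file", path))
  if (rd_uint(raw, 3L, 2L, endian) != 42L)
    stop_fg("'%s' is not a TIFF file", path)

  field_values <- function(pos) {
    type <- rd_uint(raw, pos + 2L, 2L, endian)
    count <- rd_uint(raw, pos + 4L, 4L, endian)
    size <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(size)) return(NULL)
    total <- size * count
    if (total > length(raw))
      stop_fg("corrupt TIFF field (count %d) in this file", count)
    vpos <- if (total <= 4L) pos + 8L
            else rd_uint(raw, pos + 8L, 4L, endian) + 1L
    vapply(seq_len(count) - 1L,
           function(i) rd_uint(raw, vpos + i * size, size, endian), 0)
  }

  pages <- list()
  ifd <- rd_uint(raw, 5L, 4L, endian)
  while (ifd != 0L) {
    pos0 <- ifd + 1L
    n <- rd_uint(raw, pos0, 2L, endian)
    tags <- list()
    for (i in seq_len(n)) {
      pos <- pos0 + 2L + (i - 1L) * 12L
      tag <- rd_uint(raw, pos, 2L, endian)
      tags[[as.character(tag)]] <- field_values(pos)
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    if (!is.null(g(322L)) || !is.null(g(323L)))
      stop_fg("tiled TIFF is not supported: %s", path)
    if ((g(259L, 1L))[1] != 1L)
      stop_fg("compressed TIFF is not supported: %s", path)
    if ((g(277L, 1L))[1] != 1L)
      stop_fg("only single-sample grayscale TIFF is supported: %s", path)
    bits <- (g(258L, 1L))[1]
    if (!bits %in% c(8, 16))
      stop_fg("only 8- or 16-bit TIFF is supported: %s", path)
    photometric <- (g(262L, 1L))[1]
    if (!photometric %in% c(0, 1))
      stop_fg("only grayscale TIFF is supported: %s", path)
    w <- g(256L)[1]; h <- g(257L)[1]
    offs <- g(273L); counts <- g(279L)
    if (is.null(w) || is.null(h) || is.null(offs) || is.null(counts))
      stop_fg("missing required TIFF tags in %s", path)
    px_raw <- raw(0)
    for (s in seq_along(offs))
      px_raw <- c(px_raw, raw[(offs[s] + 1L):(offs[s] + counts[s])])
    if (bits == 16) {
      b <- as.integer(px_raw)
      lo <- b[c(TRUE, FALSE)]; hi <- b[c(FALSE, TRUE)]
      v <- if (endian == "little") lo + 256 * hi else 256 * lo + hi
      v <- v / 65535
    } else {
      v <- as.integer(px_raw) / 255
    }
    if (photometric == 0) v <- 1 - v          # WhiteIsZero
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, byrow = TRUE)
    ifd <- rd_uint(raw, pos0 + 2L + n * 12L, 4L, endian)
  }
  if (!length(pages)) stop_fg("no images found in %s", path)
  if (length(pages) == 1L) pages[[1]] else pages
}
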