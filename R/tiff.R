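## Minimal multi-page grayscale TIFF codec (little-endian, uncompressed,
## one sample per pixel, one strip per page). No TIFF library is available
## in the supported R stack, so the package carries its own reader/writer
## for the narrow subset it needs: uint8/uint16 and float32/float64
## pixels. The reader additionally understands multi-strip files.

tif_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
               FLOAT = 11L, DOUBLE = 12L)
tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                   `11` = 4L, `12` = 8L)

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param path output file path.
#' @param pages a numeric matrix or a list of numeric matrices (rows = y,
#'   columns = x). All pages may have different sizes.
#' @param bits bits per sample: 8 or 16 (unsigned integer) or 32/64
#'   (IEEE float).
#' @param sample_format `"uint"` or `"float"`; defaults to `"float"` for
#'   32/64 bits and `"uint"` otherwise.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, bits = 64L, sample_format = NULL) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, TRUE)),
            bits %in% c(8L, 16L, 32L, 64L))
  if (is.null(sample_format))
    sample_format <- if (bits >= 32L) "float" else "uint"
  sf_code <- switch(sample_format, uint = 1L, float = 3L,
                    stop("sample_format must be 'uint' or 'float'"))
  if (sample_format == "float" && bits < 32L)
    stop("float samples require 32 or 64 bits")
  bytes_pp <- bits / 8L
  sizes <- vapply(pages, function(m) nrow(m) * ncol(m) * bytes_pp, 0)
  data_off <- 8 + c(0, cumsum(sizes))[seq_along(pages)]
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  ifd_start <- 8 + sum(sizes)
  ifd_off <- ifd_start + (seq_along(pages) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  ## header
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off[1])
  ## pixel data, row-major
  for (m in pages) {
    v <- as.vector(t(m))
    if (sample_format == "uint") {
      if (any(v < 0 | v > 2^bits - 1))
        stop("uint", bits, " sample out of range")
      writeBin(as.integer(round(v)), con, size = bytes_pp,
               endian = "little")
    } else {
      writeBin(as.double(v), con, size = bytes_pp, endian = "little")
    }
  }
  ## IFDs
  entry <- function(tag, type, value) {
    w16(tag); w16(type); w32(1L)
    if (type == tif_types[["SHORT"]]) { w16(value); w16(0L) }
    else w32(value)
  }
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    w16(n_tags)
    entry(256L, 4L, ncol(m))                 # ImageWidth
    entry(257L, 4L, nrow(m))                 # ImageLength
    entry(258L, 3L, bits)                    # BitsPerSample
    entry(259L, 3L, 1L)                      # Compression = none
    entry(262L, 3L, 1L)                      # Photometric = BlackIsZero
    entry(273L, 4L, data_off[i])             # StripOffsets
    entry(277L, 3L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, nrow(m))                 # RowsPerStrip
    entry(279L, 4L, sizes[i])                # StripByteCounts
    entry(339L, 3L, sf_code)                 # SampleFormat
    w32(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the subset written by [write_tiff()] plus multi-strip
#' uncompressed baseline files: little- or big-endian, one sample per
#' pixel, uint8/16/32 or float32/64.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices (rows = y, columns = x).
#' @export
read_tiff <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 8) stop("not a TIFF file: ", path)
  endian <- if (r[1] == charToRaw("I")[1]) "little" else "big"
  int_at <- function(off, size, signed = FALSE)
    readBin(r[(off + 1):(off + size)], "integer", size = size,
            endian = endian, signed = signed)
  if (int_at(2, 2) != 42L) stop("not a TIFF file: ", path)
  u16 <- function(off) int_at(off, 2L)
  u32 <- function(off) {                     # as double, offsets can be big
    b <- as.integer(r[(off + 1):(off + 4)])
    if (endian == "big") b <- rev(b)
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  read_values <- function(type, count, field_off) {
    size <- tif_type_size[[as.character(type)]]
    total <- size * count
    off <- if (total <= 4) field_off else u32(field_off)
    vapply(seq_len(count), function(k) {
      o <- off + (k - 1) * size
      switch(as.character(type),
             `3` = u16(o), `4` = u32(o), `1` = int_at(o, 1L),
             stop("unsupported TIFF tag type: ", type))
    }, 0)
  }
  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tags[[as.character(u16(off))]] <-
        list(type = u16(off + 2), count = u32(off + 4), field = off + 8)
    }
    get <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      read_values(t$type, t$count, t$field)
    }
    width <- get(256); height <- get(257)
    bits <- get(258, 1L); comp <- get(259, 1L)
    sf <- get(339, 1L); spp <- get(277, 1L)
    if (comp != 1) stop("unsupported TIFF compression: ", comp)
    if (spp != 1) stop("only single-sample (grayscale) TIFF is supported")
    offs <- get(273); counts <- get(279, width * height * bits / 8)
    bytes <- do.call(c, lapply(seq_along(offs), function(i)
      r[(offs[i] + 1):(offs[i] + counts[i])]))
    n_px <- width * height
    v <- if (sf == 3)
      readBin(bytes, "double", n = n_px, size = bits / 8, endian = endian)
    else
      readBin(bytes, "integer", n = n_px, size = bits / 8,
              endian = endian, signed = bits >= 32)
    pages[[length(pages) + 1L]] <- matrix(as.double(v), height, width,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}
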