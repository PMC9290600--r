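# --- minimal baseline TIFF ----------------------------------------------------
# Multi-page, single-strip, uncompressed 32-bit-float grayscale TIFF 6.0,
# little-endian. No TIFF library ships with this R stack, so the package
# carries its own reader/writer for exactly the subset it emits.

#' Write matrices as a multi-page float TIFF
#'
#' One page per matrix (channel), 32-bit IEEE float, single strip,
#' uncompressed, little-endian.
#'
#' @param channels List of numeric matrices with identical dimensions.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tiff <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  if (!length(channels)) stopf("at least one channel is required")
  nr <- nrow(channels[[1]]); nc <- ncol(channels[[1]])
  if (!all(vapply(channels, function(m) all(dim(m) == c(nr, nc)), logical(1))))
    stopf("all channels must share the same shape")
  n <- length(channels)
  data_size <- nr * nc * 4
  ifd_size <- 2 + 10 * 12 + 4
  # layout: 8-byte header | page data x n | IFD x n
  data_off <- 8 + (seq_len(n) - 1) * data_size
  ifd_off <- 8 + n * data_size + (seq_len(n) - 1) * ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, 2, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (m in channels)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) {            # SHORT: value in the low 2 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, 1, nc)             # ImageWidth
    entry(257, 4, 1, nr)             # ImageLength
    entry(258, 3, 1, 32)             # BitsPerSample
    entry(259, 3, 1, 1)              # Compression: none
    entry(262, 3, 1, 1)              # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[i])    # StripOffsets
    entry(277, 3, 1, 1)              # SamplesPerPixel
    entry(278, 4, 1, nr)             # RowsPerStrip
    entry(279, 4, 1, data_size)      # StripByteCounts
    entry(339, 3, 1, 3)              # SampleFormat: IEEE float
    nxt <- if (i < n) ifd_off[i + 1] else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page float TIFF written by \code{\link{write_tiff}}
#'
#' Supports the subset the writer emits (little-endian, single strip,
#' uncompressed, 32-bit float grayscale).
#'
#' @param path TIFF path.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.double(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42)
    stopf("not a little-endian TIFF: %s", path)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    nent <- u16(ifd)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2)
      val <- if (type == 3) u16(off + 8) else u32(off + 8)
      tags[[as.character(tag)]] <- val
    }
    if ((tags[["259"]] %||% 1) != 1) stopf("compressed TIFF not supported")
    if ((tags[["258"]] %||% 0) != 32 || (tags[["339"]] %||% 1) != 3)
      stopf("only 32-bit float samples are supported")
    nc <- tags[["256"]]; nr <- tags[["257"]]
    so <- tags[["273"]]
    vals <- readBin(raw[(so + 1):(so + nr * nc * 4)], "numeric",
                    n = nr * nc, size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nr, nc, byrow = TRUE)
    ifd <- u32(ifd + 2 + nent * 12)
  }
  pages
}
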