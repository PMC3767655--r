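# Minimal baseline TIFF (little-endian, uncompressed, 16-bit grayscale,
# multi-page). No TIFF-capable R package exists in this stack, so the subset
# of the format the pipeline needs is implemented directly; round-trips were
# validated against an independent TIFF implementation during development.

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' @param stack numeric matrix or `rows x cols x frames` array; values are
#'   rounded and clamped to `[0, 65535]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(stack, path) {
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1)
  d <- dim(stack)
  H <- d[1]; W <- d[2]; P <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) {        # uint16
    v <- as.integer(v)
    v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = 2, endian = "little")
  }
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  data_bytes <- 2 * H * W
  ifd_start <- 8 + P * data_bytes
  ifd_bytes <- 2 + 9 * 12 + 4
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42)
  w4(ifd_start)
  for (p in seq_len(P)) {
    m <- round(pmin(pmax(stack[, , p], 0), 65535))
    w2(as.vector(t(m)))      # TIFF scanlines are rows
  }
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0) } else w4(value)
  }
  for (p in seq_len(P)) {
    w2(9)                     # entry count
    entry(256, 4, 1, W)       # ImageWidth
    entry(257, 4, 1, H)       # ImageLength
    entry(258, 3, 1, 16)      # BitsPerSample
    entry(259, 3, 1, 1)       # Compression: none
    entry(262, 3, 1, 1)       # Photometric: BlackIsZero
    entry(273, 4, 1, 8 + (p - 1) * data_bytes)  # StripOffsets
    entry(277, 3, 1, 1)       # SamplesPerPixel
    entry(278, 4, 1, H)       # RowsPerStrip
    entry(279, 4, 1, data_bytes)                # StripByteCounts
    w4(if (p < P) ifd_start + p * ifd_bytes else 0)
  }
  invisible(path)
}

#' Read a 16-bit grayscale multi-page TIFF
#'
#' Supports the uncompressed baseline subset written by [write_tiff16()]
#' (little- or big-endian, one sample per pixel, one or more strips).
#'
#' @param path TIFF file.
#' @return Numeric array `rows x cols x frames`.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file")
  endian <- if (raw[1] == as.raw(0x49)) "little" else "big"
  rd <- function(off, n, size, signed = TRUE)
    readBin(raw[(off + 1):(off + n * size)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  magic <- rd(2, 1, 2, signed = FALSE)
  if (magic != 42) stop("not a TIFF file")
  ifd_off <- rd(4, 1, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_ent <- rd(ifd_off, 1, 2, signed = FALSE)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- rd(base, 1, 2, signed = FALSE)
      type <- rd(base + 2, 1, 2, signed = FALSE)
      count <- rd(base + 4, 1, 4)
      val <- if (type == 3 && count == 1) rd(base + 8, 1, 2, signed = FALSE)
             else rd(base + 8, 1, 4)
      # multi-valued entries (e.g. many strips) store an offset
      if (count > 1) {
        off <- rd(base + 8, 1, 4)
        val <- if (type == 3) rd(off, count, 2, signed = FALSE)
               else rd(off, count, 4)
      }
      tags[[as.character(tag)]] <- val
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    bits <- tags[["258"]]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    if (comp != 1) stop("only uncompressed TIFF supported")
    if (is.null(bits) || bits[1] != 16) stop("only 16-bit TIFF supported")
    offs <- tags[["273"]]
    counts <- tags[["279"]]
    vals <- unlist(lapply(seq_along(offs), function(i)
      rd(offs[i], counts[i] / 2, 2, signed = FALSE)))
    pages[[length(pages) + 1]] <- t(matrix(vals, nrow = W, ncol = H))
    ifd_off <- rd(ifd_off + 2 + n_ent * 12, 1, 4)
  }
  arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]]
  arr
}
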