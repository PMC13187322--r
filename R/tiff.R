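# Minimal baseline-TIFF codec (uncompressed, grayscale, multi-page).
#
# The pipeline consumes single-sample planes the way ImageJ-decomposed
# hyperstacks provide them: one page per (frame, channel). Only what the
# pipeline needs is implemented: little/big-endian baseline TIFF, strip
# layout, 8/16-bit unsigned integer and 32-bit float samples, no
# compression, one sample per pixel.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L,
               sample_format = 339L)

#' Read a multi-page grayscale TIFF
#'
#' Reads an uncompressed baseline TIFF into a list of numeric matrices
#' (one per page), promoting all sample types to double.
#'
#' @param path file path.
#' @return list of matrices indexed `[y, x]`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(rawToChar(magic), "II")) "little" else
    if (identical(rawToChar(magic), "MM")) "big" else stop("not a TIFF file")
  i16 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                            endian = endian)
  i32 <- function() readBin(con, "integer", 1, size = 4, endian = endian)
  if (i16() != 42L) stop("bad TIFF version")
  next_ifd <- i32()
  pages <- list()
  while (next_ifd != 0L) {
    seek(con, next_ifd)
    n_entries <- i16()
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- i16(); type <- i16(); count <- i32()
      val_bytes <- readBin(con, "raw", 4)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        raw = val_bytes)
    }
    next_ifd <- i32()
    getv <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) return(default)
      sz <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(e$type)]
      if (is.na(sz)) stop("unsupported TIFF field type ", e$type)
      total <- sz * e$count
      if (total <= 4L) {
        raw <- e$raw[seq_len(total)]
      } else {
        off <- readBin(e$raw, "integer", 1, size = 4, endian = endian)
        seek(con, off)
        raw <- readBin(con, "raw", total)
      }
      # R reads 4-byte integers as signed; offsets < 2^31 in practice
      readBin(raw, "integer", e$count, size = sz, signed = (sz == 4L),
              endian = endian)
    }
    w <- getv(256); h <- getv(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- getv(258, 8L)
    if (getv(259, 1L) != 1L) stop("compressed TIFF not supported")
    if (getv(277, 1L) != 1L) stop("only single-sample (grayscale) TIFF supported")
    fmt <- getv(339, 1L)
    offs <- getv(273); cnts <- getv(279)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    if (is.null(cnts)) cnts <- rep(w * h * bits / 8L / length(offs),
                                   length(offs))
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      n <- cnts[s] * 8L / bits
      vals <- c(vals, switch(
        as.character(fmt),
        `1` = , `2` = if (bits == 32L)
          readBin(con, "integer", n, size = 4, endian = endian)
        else readBin(con, "integer", n, size = bits / 8L,
                     signed = (fmt == 2L), endian = endian),
        `3` = readBin(con, "double", n, size = 4, endian = endian),
        stop("unsupported TIFF sample format ", fmt)))
    }
    if (length(vals) != w * h) stop("TIFF strip data does not match page size")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
  }
  pages
}

#' Write a multi-page grayscale TIFF
#'
#' @param pages a matrix, a list of matrices, or a 3-D array `[page, y, x]`.
#' @param path output path.
#' @param dtype `"float"` (32-bit IEEE), `"uint16"` or `"uint8"`. Integer
#'   types round and clamp to the representable range.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, dtype = c("float", "uint16", "uint8")) {
  dtype <- match.arg(dtype)
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L)
    pages <- lapply(seq_len(dim(pages)[1]), function(i) pages[i, , ])
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, TRUE)))
  bits <- switch(dtype, float = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (dtype == "float") 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  w16(42L)
  n <- length(pages)
  sizes <- vapply(pages, function(p) nrow(p) * ncol(p) * bits / 8L, 0)
  data_off <- 8 + cumsum(c(0, sizes[-n]))
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_off <- 8 + sum(sizes) + (seq_len(n) - 1L) * ifd_size
  w32(ifd_off[1])
  for (p in pages) {
    v <- as.vector(t(p))  # row-major
    if (dtype == "float") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      maxv <- if (dtype == "uint8") 255 else 65535
      writeBin(as.integer(pmin(pmax(round(v), 0), maxv)), con,
               size = bits / 8L, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (i in seq_len(n)) {
    p <- pages[[i]]
    w16(10L)
    entry(256L, 4L, 1L, ncol(p))
    entry(257L, 4L, 1L, nrow(p))
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)       # no compression
    entry(262L, 3L, 1L, 1L)       # BlackIsZero
    entry(273L, 4L, 1L, data_off[i])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, nrow(p))
    entry(279L, 4L, 1L, sizes[i])
    entry(339L, 3L, 1L, fmt)
    w32(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}
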