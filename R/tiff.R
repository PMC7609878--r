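# Minimal baseline TIFF codec: multi-page, single-sample, uncompressed.
# Covers what lambda stacks, GP maps and label maps need (uint8/16/32,
# float32/64, either byte order on read; little-endian on write). Not a
# general TIFF library: no compression, tiles, palettes or multi-sample
# pixels.

.tiff_tag <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' Read a multi-page TIFF into an array
#'
#' Supports baseline grayscale TIFF: uncompressed strips, one sample per
#' pixel, 8/16/32-bit unsigned integer, 32/64-bit IEEE float, little- or
#' big-endian. Pages must share dimensions and type.
#'
#' @param path file path.
#' @return numeric array `H x W x n_pages` (drops to a matrix only if the
#'   caller does so; the third dimension is kept even for one page).
#' @keywords internal
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L)
    stop("not a TIFF file (too short): ", path)
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rint <- function(at, size, n = 1L) {
    v <- readBin(raw[at:(at + size * n - 1L)], "integer", n = n,
                 size = size, signed = (size == 4L), endian = endian)
    if (size < 4L) v[v < 0] <- v[v < 0] + as.integer(2^(8L * size))
    v
  }
  magic <- rint(3L, 2L)
  if (magic != 42L) stop("not a TIFF file (magic != 42): ", path)
  ifd_off <- rint(5L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rint(ifd_off + 1L, 2L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      at <- ifd_off + 3L + (i - 1L) * 12L
      tag <- rint(at, 2L)
      type <- rint(at + 2L, 2L)
      count <- rint(at + 4L, 4L)
      tsize <- .tiff_type_size[[as.character(type)]]
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) at + 8L else rint(at + 8L, 4L) + 1L
      value <- if (type %in% c(3L, 4L, 1L))
        rint(voff, tsize, n = count)
      else if (type == 11L)
        readBin(raw[voff:(voff + nbytes - 1L)], "double", n = count,
                size = 4L, endian = endian)
      else NULL
      tags[[as.character(tag)]] <- value
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- rint(ifd_off + 3L + n_entries * 12L, 4L)
  }
  if (!length(pages)) stop("TIFF has no pages: ", path)

  read_page <- function(tags) {
    w <- tags[["256"]]; h <- tags[["257"]]
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    if (comp != 1L) stop("unsupported TIFF compression: ", comp)
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
    if (spp != 1L) stop("unsupported TIFF samples-per-pixel: ", spp)
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep(w * h * bits / 8 / length(offs),
                                       length(offs))
    bytes <- raw(0)
    for (k in seq_along(offs))
      bytes <- c(bytes, raw[(offs[k] + 1L):(offs[k] + counts[k])])
    size <- bits %/% 8L
    n <- w * h
    vals <- if (fmt == 3L)
      readBin(bytes, "double", n = n, size = size, endian = endian)
    else if (size == 4L) {
      # 32-bit unsigned does not fit an R integer; go via double
      u <- readBin(bytes, "integer", n = n, size = 4L, endian = endian)
      ifelse(u < 0, u + 2^32, as.numeric(u))
    } else
      as.numeric(readBin(bytes, "integer", n = n, size = size,
                         signed = (fmt == 2L || size == 4L),
                         endian = endian))
    if (fmt == 1L && size < 4L) vals <- ifelse(vals < 0, vals + 2^(bits), vals)
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }

  mats <- lapply(pages, read_page)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages differ in size; not a lambda stack")
  arr <- array(NA_real_, c(dims[1, 1], dims[2, 1], length(mats)))
  for (k in seq_along(mats)) arr[, , k] <- mats[[k]]
  arr
}

#' Write an array as a multi-page TIFF
#'
#' One page per slice of the third dimension; little-endian, uncompressed,
#' one strip per page.
#'
#' @param x numeric matrix or `H x W x C` array.
#' @param path output path.
#' @param dtype storage type: `"float32"`, `"float64"`, `"uint16"` or
#'   `"uint8"`. Integer types are range-checked.
#' @keywords internal
write_tiff <- function(x, path, dtype = c("float32", "float64",
                                          "uint16", "uint8")) {
  dtype <- match.arg(dtype)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  h <- dim(x)[1]; w <- dim(x)[2]; npage <- dim(x)[3]
  bits <- switch(dtype, float32 = 32L, float64 = 64L, uint16 = 16L,
                 uint8 = 8L)
  fmt <- if (startsWith(dtype, "float")) 3L else 1L
  size <- bits %/% 8L
  if (fmt == 1L) {
    lim <- 2^bits - 1
    if (any(x < 0 | x > lim | x != round(x), na.rm = TRUE))
      stop("values out of range for ", dtype)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(v, sz) writeBin(v, con, size = sz, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2L)
  strip_bytes <- h * w * size
  ifd_bytes <- 2L + 10L * 12L + 4L
  # layout per page: [strip][IFD]; first IFD offset follows first strip
  page_start <- 8L + (seq_len(npage) - 1L) * (strip_bytes + ifd_bytes)
  wb(page_start[1] + strip_bytes, 4L)
  for (p in seq_len(npage)) {
    vals <- as.vector(t(x[, , p]))          # TIFF is row-major
    if (fmt == 3L) wb(as.double(vals), size) else {
      if (bits == 16L && any(vals > 32767)) {
        iv <- as.integer(ifelse(vals > 32767, vals - 65536, vals))
      } else iv <- as.integer(vals)
      wb(iv, size)
    }
    entry <- function(tag, type, count, value) {
      wb(as.integer(tag), 2L); wb(as.integer(type), 2L)
      wb(as.integer(count), 4L)
      if (type == 3L) { wb(as.integer(value), 2L); wb(0L, 2L) }
      else wb(as.integer(value), 4L)
    }
    wb(10L, 2L)
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)
    entry(262L, 3L, 1L, 1L)
    entry(273L, 4L, 1L, page_start[p])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, strip_bytes)
    entry(339L, 3L, 1L, fmt)
    next_off <- if (p < npage) page_start[p + 1L] + strip_bytes else 0L
    wb(next_off, 4L)
  }
  invisible(path)
}
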