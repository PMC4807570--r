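#' @title TIFF stack input/output
#' @name stack_io
#' @description Minimal reader/writer for the uncompressed grayscale
#'   TIFF stacks the pipeline exchanges: 32-bit float for attenuation,
#'   subtraction and concentration volumes, 8-bit for binary masks.
#'   Both the multipage dialect and a directory of per-slice files
#'   (natural sort order) are supported.  Volumes are numeric 3D arrays
#'   indexed `[z, y, x]` with slice order z ascending.
NULL

# TIFF tag ids used
TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

tiff_dtype <- function(dtype) {
  switch(dtype,
         float32 = list(bits = 32L, format = 3L, size = 4L, what = "double"),
         uint16  = list(bits = 16L, format = 1L, size = 2L, what = "integer"),
         uint8   = list(bits = 8L,  format = 1L, size = 1L, what = "integer"),
         stop("unsupported dtype: ", dtype))
}

#' Write a volume as an uncompressed multipage TIFF
#'
#' @param volume numeric 3D array `[z, y, x]`.
#' @param path output file path.
#' @param dtype `"float32"` (lossless for this package's volumes),
#'   `"uint8"` or `"uint16"` (values are rounded and clipped).
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, dtype = c("float32", "uint8", "uint16")) {
  stopifnot_volume(volume)
  dtype <- match.arg(dtype)
  dt <- tiff_dtype(dtype)
  d <- dim(volume); nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (dtype != "float32") {
    top <- if (dtype == "uint8") 255 else 65535
    volume <- pmin(pmax(round(volume), 0), top)
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # layout per page: [pixel data][IFD]; header points at first IFD
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_bytes <- ny * nx * dt$size
  data_off <- function(z) 8L + (z - 1L) * (page_bytes + ifd_size)
  ifd_off <- function(z) data_off(z) + page_bytes
  writeBin(ifd_off(1L), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, value) { w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value) }
  for (z in seq_len(nz)) {
    slice <- t(volume[z, , ])                      # row-major pixel order
    if (dtype == "float32")
      writeBin(as.numeric(slice), con, size = 4, endian = "little")
    else
      writeBin(as.integer(slice), con, size = dt$size, endian = "little")
    w2(n_entries)
    entry(TIFF_TAGS[["width"]], 4L, nx)
    entry(TIFF_TAGS[["length"]], 4L, ny)
    entry(TIFF_TAGS[["bits"]], 3L, dt$bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, data_off(z))
    entry(TIFF_TAGS[["spp"]], 3L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, ny)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, page_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, dt$format)
    w4(if (z < nz) ifd_off(z + 1L) else 0L)        # next IFD
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, n, size, what = "integer")
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = size > 2L)  # 1/2-byte ints unsigned
  if (rd(2L, 1L, 2L) != 42L) stop("bad TIFF magic in ", path)
  ifd_off <- rd(4L, 1L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n <- rd(ifd_off, 1L, 2L)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd(e, 1L, 2L)
      type <- rd(e + 2L, 1L, 2L)
      count <- rd(e + 4L, 1L, 4L)
      tsz <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
      if (is.na(tsz)) next                         # skip exotic tag types
      voff <- if (count * tsz <= 4L) e + 8L else rd(e + 8L, 1L, 4L)
      tags[[as.character(tag)]] <- rd(voff, count, tsz)
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    nx <- g(256L); ny <- g(257L)
    if (is.null(nx) || is.null(ny)) stop("TIFF page missing dimensions")
    if (g(259L, 1L)[1] != 1L) stop("only uncompressed TIFF is supported")
    if (g(277L, 1L)[1] != 1L) stop("only single-sample (grayscale) TIFF supported")
    bits <- g(258L, 8L)[1]; fmt <- g(339L, 1L)[1]
    offs <- g(273L); byts <- g(279L)
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + byts[s])])
    px <- if (fmt == 3L && bits == 32L)
      readBin(buf, "double", n = nx * ny, size = 4, endian = endian)
    else if (fmt %in% c(1L, 4L) && bits %in% c(8L, 16L))
      readBin(buf, "integer", n = nx * ny, size = bits / 8L,
              endian = endian, signed = FALSE)
    else stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt, ")")
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = nx, ncol = ny))
    ifd_off <- rd(ifd_off + 2L + n * 12L, 1L, 4L)
  }
  pages
}

# Quantize to IEEE float32, the pipeline's on-disk precision.  Derived
# volumes are quantized in memory too, so a pipeline staged through
# files and a one-shot in-memory run produce bitwise-identical outputs.
as_float32 <- function(x) {
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  array(q, dim(x))
}

# order file names by embedded integers (slice_2 before slice_10)
natural_sort <- function(x) {
  key <- gsub("(\\d+)", "~\\1~", basename(x))
  parts <- strsplit(key, "~")
  pad <- vapply(parts, function(p) {
    num <- grepl("^\\d+$", p)
    p[num] <- sprintf("%020d", as.numeric(p[num]))
    paste(p, collapse = "")
  }, character(1))
  x[order(pad)]
}

#' Read a TIFF stack into a volume
#'
#' Accepts a multipage TIFF or a directory of per-slice TIFF files
#' (assembled in natural sort order).
#'
#' @param path file or directory.
#' @return numeric 3D array `[z, y, x]` with attribute `source`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
    if (!length(files)) stop("no TIFF files found in directory: ", path)
    pages <- unlist(lapply(natural_sort(files), read_tiff_pages),
                    recursive = FALSE)
  } else pages <- read_tiff_pages(path)
  if (!length(pages)) stop("no image pages found in ", path)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("mixed slice shapes in ", path)
  ny <- shapes[1, 1]; nx <- shapes[2, 1]; nz <- length(pages)
  vol <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) vol[z, , ] <- pages[[z]]
  attr(vol, "source") <- path
  vol
}
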