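## Minimal multi-page grayscale TIFF support (uncompressed). The writer
## emits 32-bit float, little-endian, one strip per page; the reader
## additionally understands both byte orders, multi-strip layouts and
## uint8/int16/uint16 samples — enough for stacks produced by common
## scientific writers. No TIFF reader is available among the installed
## R packages, hence the baseline-TIFF subset here.

write_tiff_stack <- function(pages, path) {
  # pages: (m, n, npages) array, written row-major per TIFF convention
  d <- dim(pages)
  m <- d[1]; n <- d[2]; np <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("II", con, 2, eos = NULL); w2(42L); w4(8L) # header; first IFD at 8
  # layout: header(8) | [IFD + data] per page
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_bytes <- 4L * m * n
  offset <- 8L
  for (pg in seq_len(np)) {
    data_off <- offset + ifd_size
    next_ifd <- if (pg < np) data_off + data_bytes else 0L
    tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
    w2(n_tags)
    tag(256L, 4L, 1L, n)              # ImageWidth
    tag(257L, 4L, 1L, m)              # ImageLength
    tag(258L, 3L, 1L, 32L)            # BitsPerSample
    tag(259L, 3L, 1L, 1L)             # Compression: none
    tag(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off)       # StripOffsets
    tag(278L, 4L, 1L, m)              # RowsPerStrip
    tag(279L, 4L, 1L, data_bytes)     # StripByteCounts
    tag(339L, 3L, 1L, 3L)             # SampleFormat: IEEE float
    w4(next_ifd)
    writeBin(as.numeric(t(pages[, , pg])), con, size = 4L, endian = "little")
    offset <- data_off + data_bytes
  }
  invisible(path)
}

read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("unreadable TIFF header in '", path, "'")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: '", path, "'"))
  rint <- function(off, size, n = 1L, signed = TRUE)
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = endian,
            signed = if (size <= 2L) signed else TRUE)
  if (rint(2, 2, signed = FALSE) != 42L)
    stop("not a baseline TIFF file: '", path, "'")
  ifd_off <- rint(4, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_tags <- rint(ifd_off, 2, signed = FALSE)
    tags <- list()
    for (j in seq_len(n_tags)) {
      toff <- ifd_off + 2L + (j - 1L) * 12L
      id <- rint(toff, 2, signed = FALSE)
      type <- rint(toff + 2L, 2, signed = FALSE)
      count <- rint(toff + 4L, 4)
      tsize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(tsize)) next # unsupported value type: skip tag
      voff <- if (tsize * count <= 4L) toff + 8L else rint(toff + 8L, 4)
      vals <- rint(voff, tsize, n = count, signed = FALSE)
      tags[[as.character(id)]] <- vals
    }
    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop("TIFF tag ", id, " missing in '", path, "'")
      v
    }
    wdt <- need(256); hgt <- need(257)
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    if (comp != 1L) stop("compressed TIFF not supported: '", path, "'")
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    offs <- need(273); cnts <- need(279)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw_all[(offs[s] + 1):(offs[s] + cnts[s])])
    vals <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "numeric", n = wdt * hgt, size = 4L, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = wdt * hgt, size = 1L,
                         signed = FALSE))
    } else if (bits == 16L) {
      as.numeric(readBin(buf, "integer", n = wdt * hgt, size = 2L,
                         endian = endian, signed = (fmt == 2L)))
    } else stop("unsupported TIFF sample layout (bits = ", bits,
                ", format = ", fmt, ") in '", path, "'")
    pages[[length(pages) + 1L]] <- t(matrix(vals, wdt, hgt)) # row-major file
    ifd_off <- rint(ifd_off + 2L + n_tags * 12L, 4)
  }
  if (!length(pages)) stop("TIFF file has no pages: '", path, "'")
  d <- dim(pages[[1]])
  array(unlist(pages), c(d, length(pages)))
}
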