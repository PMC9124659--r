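## MRC2014 read/write (mode 0/1/2/6), implemented directly on the binary
## layout: no MRC reader exists among the available R packages. Volumes
## are written mode 2 (32-bit float) with a standard 1024-byte header.
## MRC stores the fastest axis first (x = image columns), so stacks and
## volumes are transposed on the way in/out of the package's (m, n, z)
## row-fastest convention.

mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

write_mrc_raw <- function(data3d, path, voxel_size = 1, endian = "little") {
  d <- dim(data3d) # (nx, ny, nz) already in MRC axis order
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = endian)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = endian)
  wi(d)                    # nx ny nz
  wi(2L)                   # mode 2: float32
  wi(c(0L, 0L, 0L))        # nxstart
  wi(d)                    # mx my mz
  wf(d * voxel_size)       # cella
  wf(c(90, 90, 90))        # cellb
  wi(c(1L, 2L, 3L))        # mapc mapr maps
  wf(c(min(data3d), max(data3d), mean(data3d)))
  wi(c(0L, 0L))            # ispg, nsymbt
  writeBin(raw(100), con)  # extra
  wf(c(0, 0, 0))           # origin
  writeChar("MAP ", con, 4, eos = NULL)
  machst <- if (endian == "little") as.raw(c(0x44, 0x44, 0x00, 0x00))
            else as.raw(c(0x11, 0x11, 0x00, 0x00))
  writeBin(machst, con)
  wf(stats::sd(data3d))    # rms
  wi(0L)                   # nlabl
  writeBin(raw(800), con)  # labels
  writeBin(as.numeric(data3d), con, size = 4L, endian = endian)
  invisible(path)
}

read_mrc_raw <- function(path) {
  hdr <- readBin(path, "raw", n = 1024L)
  if (length(hdr) < 1024L) stop("unreadable MRC header in '", path, "'")
  endian <- "little"
  geti <- function(word) readBin(hdr[(4 * (word - 1) + 1):(4 * word)],
                                 "integer", size = 4L, endian = endian)
  machst <- hdr[213:214]
  if (identical(as.integer(machst), c(0x11L, 0x11L))) endian <- "big"
  mode <- geti(4)
  dims <- c(geti(1), geti(2), geti(3))
  if (!(as.character(mode) %in% names(mrc_modes)) ||
      any(dims <= 0) || any(dims > 1e5)) {
    # machst absent/bogus: retry with the other byte order
    endian <- if (endian == "little") "big" else "little"
    mode <- geti(4)
    dims <- c(geti(1), geti(2), geti(3))
  }
  if (!(as.character(mode) %in% names(mrc_modes)))
    stop("unsupported or corrupt MRC mode in '", path, "'")
  if (any(dims <= 0)) stop("unreadable MRC header in '", path, "'")
  nsymbt <- geti(24)
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 1024L + nsymbt)
  data <- switch(as.character(mode),
    `0` = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    `1` = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                             endian = endian)),
    `2` = readBin(con, "numeric", n, size = 4L, endian = endian),
    `6` = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                             endian = endian)))
  if (length(data) < n) stop("truncated MRC data in '", path, "'")
  array(data, dims)
}
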