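#' Read a tilt series from an MRC stack or multi-page TIFF
#'
#' The image format is chosen by file extension (`.mrc`, `.st`, `.rec`,
#' `.ali` for MRC; `.tif`, `.tiff` for TIFF). Angles are read from a
#' plain-text `.tlt`/`.rawtlt` file with one angle in degrees per line;
#' the count must match the stack depth. Angles that are not sorted
#' ascending trigger a warning but are never reordered silently.
#'
#' @param path image stack path.
#' @param angles_path tilt-angle file path.
#' @return a [tilt_series()].
#' @export
read_tilt_series <- function(path, angles_path) {
  angles <- read_angles(angles_path)
  ext <- tolower(tools::file_ext(path))
  stack <- if (ext %in% c("tif", "tiff")) {
    read_tiff_stack(path)
  } else {
    a <- read_mrc_raw(path) # (nx=cols, ny=rows, nz=images)
    aperm(a, c(2, 1, 3))
  }
  if (dim(stack)[3] != length(angles))
    stop("stack depth (", dim(stack)[3], ") does not match angle count (",
         length(angles), ")")
  if (is.unsorted(angles, strictly = TRUE))
    warning("tilt angles in '", angles_path, "' are not strictly increasing; ",
            "images are kept in file order")
  tilt_series(stack, angles)
}

#' Write a tilt series (MRC stack or multi-page TIFF) plus angles file
#'
#' @param b a [tilt_series()].
#' @param path output image stack path (`.mrc` or `.tif`).
#' @param angles_path optional output path for the `.tlt` angles file.
#' @param voxel_size MRC pixel size metadata.
#' @export
write_tilt_series <- function(b, path, angles_path = NULL, voxel_size = 1) {
  stopifnot(inherits(b, "tilt_series"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_tiff_stack(b$images, path)
  else write_mrc_raw(aperm(b$images, c(2, 1, 3)), path, voxel_size)
  if (!is.null(angles_path)) write_angles(b$angles_deg, angles_path)
  invisible(path)
}

#' Read / write a volume as MRC mode 2 (32-bit float)
#'
#' The package's `(m, n, z)` row-fastest arrays map to MRC's
#' column-fastest layout by an axis transpose; the round trip is lossless
#' up to float32 precision.
#'
#' @param u volume array `(m, n, z)`.
#' @param path file path.
#' @param voxel_size MRC voxel size metadata.
#' @export
write_volume <- function(u, path, voxel_size = 1) {
  u <- as_volume(u)
  write_mrc_raw(aperm(u, c(2, 1, 3)), path, voxel_size)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  aperm(read_mrc_raw(path), c(2, 1, 3))
}

#' Read / write plain-text tilt-angle files (.tlt/.rawtlt)
#'
#' One angle in degrees per line.
#'
#' @param path file path.
#' @export
read_angles <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  angles <- suppressWarnings(as.numeric(lines))
  if (anyNA(angles)) stop("non-numeric line in angles file '", path, "'")
  angles
}

#' @rdname read_angles
#' @param angles_deg numeric vector of angles.
#' @export
write_angles <- function(angles_deg, path) {
  writeLines(formatC(angles_deg, format = "fg", digits = 8), path)
  invisible(path)
}

#' Read / write per-projection shifts as TSV (angle, f0, f1)
#'
#' @param path file path.
#' @export
read_shifts <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("f0", "f1") %in% names(tab)))
    stop("shift table '", path, "' must have columns f0 and f1")
  shift_set(rbind(tab$f0, tab$f1))
}

#' @rdname read_shifts
#' @param f a [shift_set()].
#' @param angles_deg tilt angles written alongside the components.
#' @export
write_shifts <- function(f, angles_deg, path) {
  f <- shift_set(f, length(angles_deg))
  utils::write.table(
    data.frame(angle = angles_deg, f0 = f[1, ], f1 = f[2, ]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
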