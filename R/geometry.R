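#' Single-axis tilt acquisition geometry
#'
#' Describes the discretized parallel-beam geometry shared by a tilt series
#' and the reconstruction volume. The package-wide convention is:
#' volumes are `(m, n, z)` arrays indexed `[row, column, slice]`, the tilt
#' axis is the image **row** axis, and the projection at 0 degrees
#' integrates along the slice axis. Positive angles rotate right-handedly
#' about the row axis. Voxel and detector pixel sizes are equal and
#' isotropic; the unit is arbitrary.
#'
#' @param angles_deg numeric vector of tilt angles in degrees, strictly
#'   increasing, all within \[-90, 90\].
#' @param vol_shape integer vector `c(m, n, z)`: image rows, image columns,
#'   number of slices.
#' @param det_shape integer vector `c(m, n_det)`: detector rows and columns.
#'   Detector rows must equal volume rows (the tilt axis passes through
#'   unchanged). Defaults to `vol_shape[1:2]`.
#' @param voxel_size isotropic voxel size (default 1, arbitrary units).
#' @return an object of class `tilt_geometry`.
#' @export
tilt_geometry <- function(angles_deg, vol_shape,
                          det_shape = vol_shape[1:2], voxel_size = 1) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 1L || anyNA(angles_deg))
    stop("angles_deg must be a non-empty numeric vector without NA")
  if (any(diff(angles_deg) <= 0))
    stop("tilt angles must be strictly increasing")
  if (any(angles_deg < -90 | angles_deg > 90))
    stop("tilt angles must lie within [-90, 90] degrees")
  vol_shape <- as.integer(vol_shape)
  det_shape <- as.integer(det_shape)
  if (length(vol_shape) != 3L || any(vol_shape < 1L))
    stop("vol_shape must be c(m, n, z) with positive entries")
  if (length(det_shape) != 2L || any(det_shape < 1L))
    stop("det_shape must be c(m, n_det) with positive entries")
  if (det_shape[1] != vol_shape[1])
    stop("detector rows must equal volume rows (shared tilt axis)")
  structure(list(angles_deg = angles_deg, vol_shape = vol_shape,
                 det_shape = det_shape, voxel_size = as.numeric(voxel_size)),
            class = "tilt_geometry")
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("tilt_geometry: %d angles in [%g, %g] deg, volume %s, detector %s\n",
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
              paste(x$vol_shape, collapse = "x"),
              paste(x$det_shape, collapse = "x")))
  invisible(x)
}

#' Tilt series container
#'
#' A stack of projection images with their tilt angles; the observation
#' side of the tomographic inverse problem.
#'
#' @param images numeric array `(m, n_det, n_alpha)`, one image per angle.
#' @param angles_deg tilt angles in degrees, one per image.
#' @return an object of class `tilt_series` (list with `images`, `angles_deg`).
#' @export
tilt_series <- function(images, angles_deg) {
  images <- as_image_stack(images)
  angles_deg <- as.numeric(angles_deg)
  if (dim(images)[3] != length(angles_deg))
    stop("one projection image per tilt angle required (got ",
         dim(images)[3], " images, ", length(angles_deg), " angles)")
  if (!all(is.finite(images)))
    stop("tilt series images must contain finite values only")
  structure(list(images = images, angles_deg = angles_deg),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("tilt_series: %d images of %dx%d, angles [%g, %g] deg\n",
              d[3], d[1], d[2], min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

# coerce a matrix (single image) or 3D array to an (m, n, n_alpha) stack
as_image_stack <- function(images) {
  if (is.matrix(images)) dim(images) <- c(dim(images), 1L)
  if (!is.array(images) || length(dim(images)) != 3L)
    stop("images must be an (m, n, n_alpha) array")
  storage.mode(images) <- "double"
  images
}

#' Per-projection shift set
#'
#' One 2-vector of translations per tilt angle, in detector pixels.
#' Component `f0` is the horizontal shift (along image columns,
#' perpendicular to the tilt axis); `f1` is the vertical shift (along
#' image rows, parallel to the tilt axis). Applying a shift set with
#' [warp_stack()] moves image content by `+f` along each axis.
#'
#' @param shifts 2 x n_alpha numeric matrix (rows f0, f1), or a vector of
#'   length 2*n_alpha.
#' @param n_alpha optional length check.
#' @return a 2 x n_alpha matrix of class `shift_set` with rownames
#'   `c("f0", "f1")`.
#' @export
shift_set <- function(shifts, n_alpha = NULL) {
  if (is.null(dim(shifts))) shifts <- matrix(as.numeric(shifts), nrow = 2L)
  shifts <- as.matrix(shifts)
  if (nrow(shifts) != 2L) stop("shifts must be a 2 x n_alpha matrix")
  if (!all(is.finite(shifts))) stop("shifts must be finite")
  if (!is.null(n_alpha) && ncol(shifts) != n_alpha)
    stop("expected ", n_alpha, " shift vectors, got ", ncol(shifts))
  rownames(shifts) <- c("f0", "f1")
  class(shifts) <- c("shift_set", class(matrix()))
  shifts
}

#' Zero shift set
#' @param n_alpha number of tilt angles.
#' @export
shift_set_zero <- function(n_alpha) shift_set(matrix(0, 2L, n_alpha))

as_volume <- function(u, geom = NULL) {
  if (!is.array(u) || length(dim(u)) != 3L)
    stop("a volume must be a 3D (m, n, z) array")
  if (!all(is.finite(u))) stop("volume must contain finite values only")
  if (!is.null(geom) && !identical(dim(u), as.integer(geom$vol_shape)))
    stop("volume shape ", paste(dim(u), collapse = "x"),
         " does not match geometry ", paste(geom$vol_shape, collapse = "x"))
  storage.mode(u) <- "double"
  u
}

check_series_geom <- function(b, geom) {
  d <- dim(b$images)
  if (d[1] != geom$det_shape[1] || d[2] != geom$det_shape[2])
    stop("projection image shape ", d[1], "x", d[2],
         " does not match detector ", paste(geom$det_shape, collapse = "x"))
  if (d[3] != length(geom$angles_deg))
    stop("tilt series has ", d[3], " images but geometry has ",
         length(geom$angles_deg), " angles")
  invisible(TRUE)
}

#' Forward projection (discretized Radon transform)
#'
#' Applies the linear forward operator `A` of the limited-angle parallel-beam
#' model: each projection image is the set of line integrals through the
#' volume at one tilt angle. The default backend is a ray-driven projector
#' stepping along slices with linear interpolation between columns
#' (Joseph's method) and path weight `1/cos(angle)` per slice step.
#'
#' @param u volume array `(m, n, z)` matching `geom$vol_shape`.
#' @param geom a [tilt_geometry()].
#' @param backend backend name (see [backend_register()]); default `"joseph"`.
#' @return a [tilt_series()] holding `A u`.
#' @export
forward_project <- function(u, geom, backend = "joseph") {
  u <- as_volume(u, geom)
  be <- backend_get(backend)
  stack <- be$project(u, geom)
  tilt_series(stack, geom$angles_deg)
}

#' Back projection (adjoint operator)
#'
#' Applies `A*`, the exact algebraic adjoint of [forward_project()] for the
#' same backend and geometry: `<A u, b> == <u, A* b>` up to rounding.
#'
#' @param b a [tilt_series()] or `(m, n_det, n_alpha)` array matching `geom`.
#' @param geom a [tilt_geometry()].
#' @param backend backend name; default `"joseph"`.
#' @return a volume array `(m, n, z)`.
#' @export
back_project <- function(b, geom, backend = "joseph") {
  stack <- stack_of(b)
  if (inherits(b, "tilt_series")) check_series_geom(b, geom)
  d <- dim(stack)
  if (d[1] != geom$det_shape[1] || d[2] != geom$det_shape[2] ||
      d[3] != length(geom$angles_deg))
    stop("projection stack does not match geometry")
  be <- backend_get(backend)
  be$backproject(stack, geom)
}

stack_of <- function(b) {
  if (inherits(b, "tilt_series")) b$images else as_image_stack(b)
}
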