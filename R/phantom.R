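#' Specification of a geometric 3D phantom
#'
#' The validation phantom is a Shepp-Logan-style assembly of a few basic
#' solid geometric shapes (cubes, cuboids, spheres, ellipsoids) placed
#' randomly in a cubic volume, each with a constant intensity; overlaps are
#' resolved last-writer-wins and the background is zero.
#'
#' @param size cube edge length in voxels (>= 16).
#' @param n_shapes number of shapes (>= 1, default 12).
#' @param shape_kinds subset of `c("cube", "cuboid", "sphere", "ellipsoid")`.
#' @param intensity_range shape intensities are drawn uniformly from this
#'   interval (default `c(0.3, 1)`).
#' @param seed integer RNG seed; the phantom is deterministic in it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64, n_shapes = 12,
                         shape_kinds = c("cube", "cuboid", "sphere", "ellipsoid"),
                         intensity_range = c(0.3, 1), seed = 1L) {
  if (size < 16) stop("size must be >= 16")
  if (n_shapes < 1) stop("n_shapes must be >= 1")
  shape_kinds <- match.arg(shape_kinds,
                           c("cube", "cuboid", "sphere", "ellipsoid"),
                           several.ok = TRUE)
  structure(list(size = as.integer(size), n_shapes = as.integer(n_shapes),
                 shape_kinds = shape_kinds,
                 intensity_range = as.numeric(intensity_range),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random rotation matrix via QR of a Gaussian matrix (sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

#' Generate a geometric 3D phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return volume array `(size, size, size)` with attribute `"shapes"`
#'   holding the sampled shape parameters.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  with_seed(spec$seed, {
    u <- array(0, c(s, s, s))
    ax <- seq_len(s) - (s + 1) / 2
    gr <- rep(ax, times = s * s)
    gc <- rep(rep(ax, each = s), times = s)
    gk <- rep(ax, each = s * s)
    shapes <- vector("list", spec$n_shapes)
    for (j in seq_len(spec$n_shapes)) {
      kind <- sample(spec$shape_kinds, 1)
      centre <- stats::runif(3, -0.3, 0.3) * s
      half <- switch(kind,
        cube = rep(stats::runif(1, 0.06, 0.18) * s, 3),
        sphere = rep(stats::runif(1, 0.06, 0.18) * s, 3),
        cuboid = stats::runif(3, 0.05, 0.2) * s,
        ellipsoid = stats::runif(3, 0.05, 0.2) * s)
      rot <- if (kind %in% c("cuboid", "ellipsoid")) random_rotation()
             else diag(3)
      val <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
      y1 <- rot[1, 1] * (gr - centre[1]) + rot[2, 1] * (gc - centre[2]) +
            rot[3, 1] * (gk - centre[3])
      y2 <- rot[1, 2] * (gr - centre[1]) + rot[2, 2] * (gc - centre[2]) +
            rot[3, 2] * (gk - centre[3])
      y3 <- rot[1, 3] * (gr - centre[1]) + rot[2, 3] * (gc - centre[2]) +
            rot[3, 3] * (gk - centre[3])
      inside <- if (kind %in% c("cube", "cuboid"))
        abs(y1) <= half[1] & abs(y2) <= half[2] & abs(y3) <= half[3]
      else
        (y1 / half[1])^2 + (y2 / half[2])^2 + (y3 / half[3])^2 <= 1
      u[inside] <- val
      shapes[[j]] <- list(kind = kind, centre = centre, half = half,
                          value = val)
    }
    attr(u, "shapes") <- shapes
    u
  })
}

#' Simulate a shifted limited-angle tilt series of a phantom
#'
#' Reproduces the validation protocol: project the phantom over a limited
#' angular range, then displace every projection image by an independent
#' 2D shift drawn from `Normal(0, shift_sigma^2)` per component (standard
#' normal by default, continuous sub-pixel values).
#'
#' @param spec a [phantom_spec()].
#' @param geom optional [tilt_geometry()]; defaults to angles -60..60 in
#'   1-degree steps (121 projections) over a cubic volume.
#' @param shift_sigma standard deviation of the induced shifts in pixels
#'   (default 1; 0 gives a clean series).
#' @param seed RNG seed for the shifts (defaults to `spec$seed + 1`).
#' @param backend projector backend name.
#' @return list with `b` (shifted [tilt_series()]), `f_true`
#'   ([shift_set()] of induced displacements), `u_gt` (phantom volume),
#'   `clean` (unshifted tilt series) and `geom`.
#' @export
make_dataset <- function(spec = phantom_spec(), geom = NULL, shift_sigma = 1,
                         seed = spec$seed + 1L, backend = "joseph") {
  if (shift_sigma < 0) stop("shift_sigma must be >= 0")
  u_gt <- make_phantom(spec)
  if (is.null(geom))
    geom <- tilt_geometry(seq(-60, 60, by = 1), dim(u_gt))
  clean <- forward_project(u_gt, geom, backend)
  na <- length(geom$angles_deg)
  f_true <- with_seed(seed,
    shift_set(matrix(stats::rnorm(2 * na, 0, shift_sigma), 2L, na)))
  b <- if (shift_sigma > 0) warp_stack(clean, f_true) else clean
  list(b = b, f_true = f_true, u_gt = u_gt, clean = clean, geom = geom)
}
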