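#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels.
#'
#' @param u volume (or any numeric array).
#' @param ref reference of the same shape.
#' @param peak peak value; `"auto"` (default) uses `max(ref)`.
#' @return PSNR in dB; `Inf` when `u == ref`.
#' @export
psnr <- function(u, ref, peak = "auto") {
  if (!identical(dim(u), dim(ref))) stop("u and ref must have the same shape")
  if (identical(peak, "auto")) peak <- max(ref)
  mse <- mean((u - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Gauge component of a shift set
#'
#' Projection of a shift set onto the unidentifiable 3D-translation
#' subspace: a global object translation `(dx, dz)` in the tilt plane maps
#' to horizontal shifts `dx * cos(a) - dz * sin(a)`, and a translation
#' `dr` along the tilt axis to a constant vertical shift. Least-squares
#' fit per component.
#'
#' @param f a [shift_set()].
#' @param angles_deg tilt angles in degrees.
#' @return 2 x n_alpha matrix: the gauge part of `f`.
#' @export
shift_gauge_component <- function(f, angles_deg) {
  f <- shift_set(f, length(angles_deg))
  a <- angles_deg * pi / 180
  X <- cbind(cos(a), sin(a))
  g0 <- X %*% qr.coef(qr(X), f[1, ])
  rbind(as.numeric(g0), rep(mean(f[2, ]), length(a)))
}

#' Fit the 3D-translation gauge coefficients of a shift set
#'
#' Least-squares fit of the horizontal component against
#' `dx * cos(a) - dz * sin(a)` and of the vertical component against a
#' constant `dr`. Applied to a shift *error* `f_est - f_true`, the
#' negated coefficients give the global offset of the reconstruction
#' relative to the ground-truth object (see [volume_translate()]).
#'
#' @param f a [shift_set()].
#' @param angles_deg tilt angles in degrees.
#' @return named numeric vector `c(dx, dz, dr)`: translation along image
#'   columns, along the slice (depth) axis, and along image rows, in
#'   voxels.
#' @export
shift_gauge_fit <- function(f, angles_deg) {
  f <- shift_set(f, length(angles_deg))
  a <- angles_deg * pi / 180
  co <- qr.coef(qr(cbind(cos(a), -sin(a))), f[1, ])
  c(dx = unname(co[1]), dz = unname(co[2]), dr = mean(f[2, ]))
}

#' Translate a volume by a sub-voxel 3D shift
#'
#' Separable (trilinear) interpolation with edge replication; content
#' moves by `+shift`. Used to register a reconstruction to a reference
#' over the unidentifiable translation gauge before voxelwise comparison.
#'
#' @param u volume array `(m, n, z)`.
#' @param shift numeric `c(rows, columns, slices)` in voxels.
#' @return translated volume, same shape.
#' @export
volume_translate <- function(u, shift) {
  d <- dim(u)
  interp_axis <- function(x, delta, axis) {
    if (delta == 0) return(x)
    n <- d[axis]
    xi <- seq_len(n) - delta
    i0 <- pmin(pmax(floor(xi), 1), n)
    i1 <- pmin(i0 + 1, n)
    w <- pmin(pmax(xi - floor(xi), 0), 1)
    pick <- function(idx) switch(axis, x[idx, , , drop = FALSE],
                                 x[, idx, , drop = FALSE],
                                 x[, , idx, drop = FALSE])
    wfull <- switch(axis, rep(w, times = d[2] * d[3]),
                    rep(rep(w, each = d[1]), times = d[3]),
                    rep(w, each = d[1] * d[2]))
    array((1 - wfull) * pick(i0) + wfull * pick(i1), d)
  }
  for (ax in 1:3) u <- interp_axis(u, shift[ax], ax)
  u
}

#' Per-component shift error statistics
#'
#' Errors `e = f_est - f_true` per shift component, optionally after
#' removing the unidentifiable alignment gauge: the absolute object
#' position cannot be recovered, which leaves a constant offset in the
#' vertical component `f1` and a tilt-angle-dependent (approximately
#' linear in `tan(angle)`) offset in the horizontal component `f0`.
#' `gauge = "constant"` subtracts each component's mean error;
#' `gauge = "linear_tan"` additionally removes a least-squares fit of the
#' `f0` error against `tan(angle)`; `gauge = "translation"` removes the
#' exact 3D-translation gauge ([shift_gauge_component()]). The default
#' `gauge = "none"` reports raw differences.
#'
#' Because the "std." of a squared-error table is ambiguous, both the
#' standard deviation of squared errors (`std_sq`) and of absolute errors
#' (`std_abs`) are reported.
#'
#' @param f_est estimated [shift_set()].
#' @param f_true true [shift_set()].
#' @param gauge one of `"none"`, `"constant"`, `"linear_tan"`.
#' @param angles_deg tilt angles, required for `gauge = "linear_tan"`.
#' @return data.frame with one row per component (`f0`, `f1`) and columns
#'   `mse`, `std_sq`, `mae`, `std_abs`, `max_ae`.
#' @export
shift_error_stats <- function(f_est, f_true,
                              gauge = c("none", "constant", "linear_tan",
                                        "translation"),
                              angles_deg = NULL) {
  gauge <- match.arg(gauge)
  f_est <- shift_set(f_est); f_true <- shift_set(f_true, ncol(f_est))
  e <- unclass(f_est) - unclass(f_true)
  if (gauge %in% c("constant", "linear_tan"))
    e <- e - rowMeans(e)
  if (gauge == "linear_tan") {
    if (is.null(angles_deg)) stop("angles_deg required for gauge = 'linear_tan'")
    t <- tan(angles_deg * pi / 180)
    fit <- stats::lm.fit(cbind(1, t), e[1, ])
    e[1, ] <- fit$residuals
  }
  if (gauge == "translation") {
    if (is.null(angles_deg)) stop("angles_deg required for gauge = 'translation'")
    e <- e - shift_gauge_component(shift_set(e), angles_deg)
  }
  stats_row <- function(err) {
    data.frame(mse = mean(err^2), std_sq = stats::sd(err^2),
               mae = mean(abs(err)), std_abs = stats::sd(abs(err)),
               max_ae = max(abs(err)))
  }
  out <- rbind(stats_row(e[1, ]), stats_row(e[2, ]))
  cbind(data.frame(component = c("f0", "f1")), out)
}
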