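#' Tilt-dependent reconstruction mask
#'
#' Binary per-pixel weights on projection space. At tilt angle `a` only a
#' centred band of columns of half-width `(n_det/2) * cos(|a|) - margin_px`
#' maps onto the reconstructed volume (higher tilt compresses the imaged
#' structures), so pixels outside it are excluded from the data term and
#' from the shift estimation. Rows keep a fixed `margin_px` border.
#'
#' @param geom a [tilt_geometry()].
#' @param margin_px non-negative integer safety margin (default 2).
#' @return array `(m, n_det, n_alpha)` of 0/1 weights, class `tilt_mask`.
#' @export
build_mask <- function(geom, margin_px = 2) {
  if (margin_px < 0) stop("margin_px must be >= 0")
  m <- geom$det_shape[1]; n <- geom$det_shape[2]
  ang <- geom$angles_deg
  centre_c <- (n - 1) / 2
  col_off <- abs(seq_len(n) - 1 - centre_c)
  row_ok <- seq_len(m) > margin_px & seq_len(m) <= m - margin_px
  w <- array(0, c(m, n, length(ang)))
  for (i in seq_along(ang)) {
    hw <- (n / 2) * cos(abs(ang[i]) * pi / 180) - margin_px
    if (hw <= 0)
      stop("mask band width <= 0 at angle ", ang[i],
           " deg (detector too small or margin too large)")
    w[row_ok, col_off <= hw, i] <- 1
  }
  class(w) <- c("tilt_mask", class(array()))
  w
}

#' Closed-form per-angle shift update
#'
#' Recomputes every projection's 2D shift as the exact minimizer of the
#' masked, linearized data-fidelity term with the reconstruction held
#' fixed. Because the data term separates over projections, the `2 n_alpha`
#' unknowns decouple into one 2x2 normal-equation solve per tilt angle
#' (the Lucas-Kanade normal form): with `b_f = W(b, f_i)`,
#' `G = central_gradient(b_f)` and residual `e = A u - b_f`,
#' `f_new = f_i - H^-1 sum(G M e)` where `H = sum(G M G^T)` over the masked
#' pixels of each image. Gradients are recomputed from the freshly warped
#' stack on every call, not cached.
#'
#' @param u current reconstruction volume `(m, n, z)`.
#' @param b observed (unwarped) [tilt_series()].
#' @param f_i current shift estimate (warp frame: `warp_stack(b, f_i)` is
#'   the aligned stack).
#' @param mask binary mask from [build_mask()].
#' @param geom a [tilt_geometry()].
#' @param backend projector backend name.
#' @param Au optional precomputed `forward_project(u, geom)` to avoid a
#'   second projection per iteration.
#' @param cond_max eigenvalues of a per-angle normal matrix below
#'   `max_eigenvalue / cond_max` are treated as zero: the update keeps the
#'   previous shift along such unidentifiable directions (with a warning;
#'   this signals a gradient-free masked region) instead of zeroing it,
#'   preserving the monotone behaviour of the outer loop.
#' @return updated [shift_set()] (same warp frame as `f_i`).
#' @export
shift_update <- function(u, b, f_i, mask, geom, backend = "joseph",
                         Au = NULL, cond_max = 1e8) {
  stopifnot(inherits(b, "tilt_series"))
  check_series_geom(b, geom)
  d <- dim(b$images)
  f_i <- shift_set(f_i, d[3])
  if (is.null(Au)) Au <- forward_project(u, geom, backend)
  Au <- stack_of(Au)
  b_f <- warp_stack(b$images, f_i)
  g <- central_gradient(b_f)
  npx <- d[1] * d[2]; na <- d[3]
  mk <- array(as.numeric(mask), d)
  g0 <- matrix(g[, , , 1], npx, na); g1 <- matrix(g[, , , 2], npx, na)
  mm <- matrix(mk, npx, na)
  e <- matrix(Au - b_f, npx, na)
  h00 <- colSums(g0 * g0 * mm); h11 <- colSums(g1 * g1 * mm)
  h01 <- colSums(g0 * g1 * mm)
  r0 <- colSums(g0 * mm * e); r1 <- colSums(g1 * mm * e)
  f_new <- unclass(f_i)
  degenerate <- logical(na)
  for (i in seq_len(na)) {
    H <- matrix(c(h00[i], h01[i], h01[i], h11[i]), 2L, 2L)
    ev <- eigen(H, symmetric = TRUE)
    keep <- ev$values > max(ev$values[1], 0) / cond_max & ev$values > 0
    if (!any(keep)) { degenerate[i] <- TRUE; next }
    # truncated pseudoinverse: exact minimizer along identifiable
    # directions, previous shift kept along (near-)null directions
    V <- ev$vectors[, keep, drop = FALSE]
    step <- V %*% ((crossprod(V, c(r0[i], r1[i]))) / ev$values[keep])
    f_new[, i] <- f_new[, i] - step
    degenerate[i] <- !all(keep)
  }
  if (any(degenerate))
    warning("rank-deficient shift normal matrix at angle(s) ",
            paste(signif(geom$angles_deg[degenerate], 4), collapse = ", "),
            "; previous shift kept along unidentifiable directions")
  shift_set(f_new)
}
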