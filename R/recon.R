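#' Reconstruction configuration
#'
#' Bundles the tunable parameters of the joint alignment/reconstruction
#' scheme.
#'
#' @param lambda positive total-variation weight balancing the regularizer
#'   against the masked data fidelity. The default (0.5) was fixed once by
#'   a small sweep on the default phantom (PSNR plateaus for lambda in
#'   roughly \[0.3, 1\] at the phantom's unit intensity scale); it is a
#'   configuration value, not a claim.
#' @param n_iter number of outer iterations N (each = one primal-dual step
#'   plus one closed-form shift recomputation). Default 2000.
#' @param precond_alpha diagonal-preconditioning exponent in \[0, 2\]
#'   (default 1: row/column absolute sums).
#' @param margin_px mask margin in pixels (default 2), see [build_mask()].
#' @param backend projector backend name (default `"joseph"`).
#' @param seed integer seed for any randomized component (the core loop is
#'   deterministic; the seed is consumed by simulation helpers and the CLI).
#' @param theta primal extrapolation parameter (default 1).
#' @param nonneg clamp the reconstruction to non-negative values after each
#'   primal step (default FALSE: unconstrained).
#' @param prealign run cross-correlation pre-alignment for the initial
#'   shifts (default TRUE); if FALSE the initial shifts are zero.
#' @param freeze_shifts skip the shift recomputation entirely, holding the
#'   initial shifts fixed (used for ablation baselines).
#' @param early_stop_tol optional early stop: terminate once the maximum
#'   per-angle shift change drops below this many pixels (default NULL,
#'   i.e. run all `n_iter` iterations, which is the reference behaviour).
#' @param gauge_fix centre the initial shift corrections by removing their
#'   projection onto the unidentifiable 3D-translation gauge subspace
#'   (default TRUE), keeping the reconstruction centred in the volume.
#' @param record_every record energy/PSNR diagnostics every this many
#'   iterations (default 10; shift traces are always recorded).
#' @param verbose print per-record progress lines.
#' @return a list of class `flara_config`.
#' @export
flara_config <- function(lambda = 0.5, n_iter = 2000, precond_alpha = 1,
                         margin_px = 2, backend = "joseph", seed = 1L,
                         theta = 1, nonneg = FALSE, prealign = TRUE,
                         freeze_shifts = FALSE, early_stop_tol = NULL,
                         gauge_fix = TRUE, record_every = 10,
                         verbose = FALSE) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (precond_alpha < 0 || precond_alpha > 2)
    stop("precond_alpha must lie in [0, 2]")
  structure(list(lambda = lambda, n_iter = as.integer(n_iter),
                 precond_alpha = precond_alpha, margin_px = margin_px,
                 backend = backend, seed = as.integer(seed), theta = theta,
                 nonneg = isTRUE(nonneg), prealign = isTRUE(prealign),
                 freeze_shifts = isTRUE(freeze_shifts),
                 early_stop_tol = early_stop_tol,
                 gauge_fix = isTRUE(gauge_fix),
                 record_every = as.integer(record_every),
                 verbose = isTRUE(verbose)),
            class = "flara_config")
}

#' 3D forward-difference gradient
#'
#' Forward differences along rows, columns and slices with a Neumann
#' (zero-difference) boundary at each far edge.
#'
#' @param u volume array `(m, n, z)`.
#' @return array `(m, n, z, 3)`.
#' @export
grad3d <- function(u) {
  d <- dim(u)
  array(grad3d_cpp(as.numeric(u), d[1], d[2], d[3]), c(d, 3L))
}

#' 3D divergence (negative adjoint of [grad3d()])
#'
#' Satisfies `sum(grad3d(u) * p) == -sum(u * div3d(p))` exactly, which is
#' the discrete integration-by-parts identity the primal-dual scheme needs.
#'
#' @param p array `(m, n, z, 3)`.
#' @return volume array `(m, n, z)`.
#' @export
div3d <- function(p) {
  d <- dim(p)
  if (length(d) != 4L || d[4] != 3L) stop("p must be an (m, n, z, 3) array")
  array(div3d_cpp(as.numeric(p), d[1], d[2], d[3]), d[1:3])
}

#' Proximal map of the dualized quadratic data term
#'
#' The data fidelity enters the saddle-point problem through its convex
#' conjugate, whose proximal map is the elementwise contraction
#' `q / (1 + sigma_q)`. The linear term (the masked, warped observation) is
#' folded into the preceding dual ascent step.
#'
#' @param q_tilde dual variable after the ascent step.
#' @param sigma_q dual step size(s), elementwise.
#' @return proximal point, same shape as `q_tilde`.
#' @export
prox_data_dual <- function(q_tilde, sigma_q) q_tilde / (1 + sigma_q)

#' Projection onto the TV dual ball
#'
#' Projects each voxel's dual 3-vector onto the Euclidean ball of radius
#' `lambda`: `p_v / max(1, |p_v|_2 / lambda)` (the proximal map of the
#' indicator of the `(2, inf)`-norm ball).
#'
#' @param p array `(m, n, z, 3)`.
#' @param lambda ball radius (> 0).
#' @return projected array, same shape.
#' @export
proj_l2inf_ball <- function(p, lambda) {
  if (lambda <= 0) stop("lambda must be > 0")
  d <- dim(p)
  nv <- prod(d[1:3])
  pm <- matrix(p, nv, 3L)
  nrm <- sqrt(rowSums(pm * pm))
  s <- pmax(1, nrm / lambda)
  array(pm / s, d)
}

#' Diagonal preconditioners for the stacked operator
#'
#' Per-element primal and dual step sizes for the saddle-point problem with
#' stacked operator `K = [M o A; grad]`: dual steps are inverse row sums
#' `1 / sum_j |K_ij|^(2 - alpha)`, primal steps inverse column sums
#' `1 / sum_i |K_ij|^alpha` (alpha = 1 by default). These choices satisfy
#' the preconditioned primal-dual convergence condition without estimating
#' an operator norm. The mask is applied inside the sums (rows of `A` that
#' the mask removes contribute nothing to the column sums); fully masked
#' rows receive the unmasked row sum so no step size degenerates, and any
#' remaining zero sums are floored at 1e-6.
#'
#' @param geom a [tilt_geometry()].
#' @param mask binary mask from [build_mask()].
#' @param alpha exponent in \[0, 2\] (default 1).
#' @param backend projector backend name.
#' @return list with `tau` (volume-shaped primal steps), `sigma_p`
#'   (`(m, n, z, 3)` TV dual steps) and `sigma_q` (projection-shaped data
#'   dual steps), all strictly positive.
#' @export
init_preconditioners <- function(geom, mask, alpha = 1, backend = "joseph") {
  if (alpha < 0 || alpha > 2) stop("alpha must lie in [0, 2]")
  be <- backend_get(backend)
  floor_ <- 1e-6
  d <- geom$vol_shape
  na <- length(geom$angles_deg)
  mask_stack <- array(as.numeric(mask), c(geom$det_shape, na))

  ws_row <- backend_weight_sums(be, geom, 2 - alpha, mask_stack)$row
  ws_col <- backend_weight_sums(be, geom, alpha, mask_stack)$col

  row_masked <- ws_row * mask_stack
  row_eff <- ifelse(row_masked > 0, row_masked, pmax(ws_row, floor_))
  sigma_q <- 1 / pmax(row_eff, floor_)

  # gradient block: every row of grad has entries {-1, +1} except the
  # Neumann far-edge rows, which are identically zero
  m <- d[1]; n <- d[2]; z <- d[3]
  rs <- array(2, c(d, 3L))
  rs[m, , , 1] <- 0; rs[, n, , 2] <- 0; rs[, , z, 3] <- 0
  sigma_p <- 1 / pmax(rs, floor_)

  # each voxel appears with +1 in its own row (unless at the far edge) and
  # with -1 in the previous voxel's row (unless at the near edge), per axis
  ax_r <- c(rep(2, m)); ax_r[1] <- 1; ax_r[m] <- 1
  ax_c <- c(rep(2, n)); ax_c[1] <- 1; ax_c[n] <- 1
  ax_z <- c(rep(2, z)); ax_z[1] <- 1; ax_z[z] <- 1
  cs_grad <- outer(outer(ax_r, ax_c, "+"), ax_z, "+")
  tau <- 1 / pmax(ws_col + cs_grad, floor_)

  list(tau = array(tau, d), sigma_p = sigma_p,
       sigma_q = array(sigma_q, c(geom$det_shape, na)))
}

#' Initialize the primal-dual state
#'
#' Zero primal and dual variables (`u = 0`, `p = 0`, `q = 0`) with the
#' diagonal preconditioners of [init_preconditioners()].
#'
#' @param geom a [tilt_geometry()].
#' @param mask binary mask from [build_mask()].
#' @param cfg a [flara_config()].
#' @return list of class `pd_state`.
#' @export
pd_state_init <- function(geom, mask, cfg = flara_config()) {
  pre <- init_preconditioners(geom, mask, cfg$precond_alpha, cfg$backend)
  d <- geom$vol_shape
  na <- length(geom$angles_deg)
  structure(list(u = array(0, d), u_bar = array(0, d),
                 p = array(0, c(d, 3L)),
                 q = array(0, c(geom$det_shape, na)),
                 tau = pre$tau, sigma_p = pre$sigma_p, sigma_q = pre$sigma_q,
                 theta = cfg$theta),
            class = "pd_state")
}

#' One preconditioned primal-dual iteration
#'
#' A single iteration of the saddle-point solver for the masked,
#' TV-regularized least-squares reconstruction sub-problem with the warped
#' observations `b_f` held fixed:
#' dual ascent `q <- prox(q + sigma_q * M (A u_bar - b_f))`,
#' `p <- proj(p + sigma_p * grad u_bar)`; primal descent
#' `u <- u - tau * (A* (M q) - div p)`; extrapolation
#' `u_bar <- u + theta (u - u_prev)`. The reconstruction is unconstrained
#' unless `cfg$nonneg` is set.
#'
#' @param state a `pd_state` (see [pd_state_init()]); dual variables are
#'   carried across outer iterations even as the shifts (and hence `b_f`)
#'   change.
#' @param b_f warped tilt series (array or [tilt_series()]).
#' @param mask binary mask.
#' @param geom a [tilt_geometry()].
#' @param cfg a [flara_config()].
#' @param Au_bar optional precomputed projection of `state$u_bar`.
#' @return updated `pd_state`.
#' @export
pd_iteration <- function(state, b_f, mask, geom, cfg = flara_config(),
                         Au_bar = NULL) {
  bstack <- stack_of(b_f)
  mk <- array(as.numeric(mask), dim(bstack))
  if (is.null(Au_bar)) Au_bar <- stack_of(forward_project(state$u_bar, geom, cfg$backend))
  q <- prox_data_dual(state$q + state$sigma_q * mk * (Au_bar - bstack),
                      state$sigma_q)
  p <- proj_l2inf_ball(state$p + state$sigma_p * grad3d(state$u_bar),
                       cfg$lambda)
  descent <- back_project(mk * q, geom, cfg$backend) - div3d(p)
  u_new <- state$u - state$tau * descent
  if (cfg$nonneg) u_new <- pmax(u_new, 0)
  if (!all(is.finite(u_new)))
    stop("primal-dual iteration diverged (non-finite reconstruction); ",
         "check step sizes and input scaling")
  state$u_bar <- u_new + state$theta * (u_new - state$u)
  state$u <- u_new
  state$p <- p
  state$q <- q
  state
}

#' Primal energy of the reconstruction sub-problem
#'
#' `0.5 * ||M (A u - b_f)||^2 + lambda * ||grad u||_{2,1}` — the objective
#' the primal-dual scheme minimizes for fixed shifts.
#'
#' @param u volume.
#' @param b_f warped tilt series (array or [tilt_series()]).
#' @param mask binary mask.
#' @param geom a [tilt_geometry()].
#' @param lambda TV weight.
#' @param backend projector backend name.
#' @param Au optional precomputed projection of `u`.
#' @return scalar energy.
#' @export
primal_energy <- function(u, b_f, mask, geom, lambda, backend = "joseph",
                          Au = NULL) {
  bstack <- stack_of(b_f)
  if (is.null(Au)) Au <- stack_of(forward_project(u, geom, backend))
  Au <- stack_of(Au)
  res <- as.numeric(mask) * (Au - bstack)
  g <- grad3d(u)
  d <- dim(g)
  gm <- matrix(g, prod(d[1:3]), 3L)
  0.5 * sum(res^2) + lambda * sum(sqrt(rowSums(gm * gm)))
}
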