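#' Translate each projection image by its per-angle shift
#'
#' Applies the warping operator `W(b, f)`: image `i` is translated by
#' `f[, i]` with bilinear (sub-pixel) interpolation. Positive shifts move
#' image content toward increasing pixel index (`f0` along columns, `f1`
#' along rows). Samples falling outside the image support are filled by
#' edge replication, which avoids manufacturing artificial gradients at
#' the boundary (the reconstruction mask excludes the boundary anyway).
#'
#' @param b a [tilt_series()] or `(m, n, n_alpha)` array.
#' @param f a [shift_set()] (2 x n_alpha) or anything coercible to one.
#' @return same type as `b`, warped.
#' @export
warp_stack <- function(b, f) {
  stack <- stack_of(b)
  d <- dim(stack)
  f <- shift_set(f, n_alpha = d[3])
  out <- array(warp_stack_cpp(as.numeric(stack), d[1], d[2], d[3],
                              f[1, ], f[2, ]), d)
  if (inherits(b, "tilt_series")) tilt_series(out, b$angles_deg) else out
}

#' Per-image spatial gradients by central differences
#'
#' Central differences in the interior, one-sided at image borders. The
#' central stencil is what keeps the gradient co-located with the pixel
#' grid, which the linearized warping model relies on.
#'
#' @param b a [tilt_series()] or `(m, n, n_alpha)` array.
#' @return array `(m, n, n_alpha, 2)`: component 1 is the derivative along
#'   columns (pairs with shift component `f0`), component 2 along rows
#'   (pairs with `f1`).
#' @export
central_gradient <- function(b) {
  stack <- stack_of(b)
  d <- dim(stack)
  array(central_gradient_cpp(as.numeric(stack), d[1], d[2], d[3]),
        c(d, 2L))
}

#' First-order (linearized) warping
#'
#' Taylor expansion of `W(b, f)` around a current shift estimate `f_i`:
#' `W(b, f) ~ W(b, f_i) - <grad W(b, f_i), f - f_i>`. The minus sign
#' follows from the sampling convention of [warp_stack()] (content moves
#' by `+f`, so the image function is sampled at `x - f`); the identity is
#' exact for affine images, which pins the convention.
#'
#' @param b a [tilt_series()] or image stack.
#' @param f_i shift estimate the expansion is centred on.
#' @param f target shifts.
#' @return same type as `b`: the linearized warp evaluated at `f`.
#' @export
linearized_warp <- function(b, f_i, f) {
  stack <- stack_of(b)
  d <- dim(stack)
  f_i <- shift_set(f_i, d[3]); f <- shift_set(f, d[3])
  warped <- array(warp_stack_cpp(as.numeric(stack), d[1], d[2], d[3],
                                 f_i[1, ], f_i[2, ]), d)
  g <- array(central_gradient_cpp(as.numeric(warped), d[1], d[2], d[3]),
             c(d, 2L))
  df0 <- rep(f[1, ] - f_i[1, ], each = d[1] * d[2])
  df1 <- rep(f[2, ] - f_i[2, ], each = d[1] * d[2])
  out <- warped - array(g[, , , 1] * df0 + g[, , , 2] * df1, d)
  if (inherits(b, "tilt_series")) tilt_series(out, b$angles_deg) else out
}

#' Cosine stretch of a projection image
#'
#' Dilates an image along the axis perpendicular to the tilt axis (the
#' column axis) by `1/cos(angle)`, undoing the foreshortening of tilted
#' projections. Output keeps the input pixel grid; bilinear interpolation
#' with edge replication.
#'
#' @param image numeric matrix `(m, n)`.
#' @param angle_deg tilt angle, `|angle| < 90`.
#' @return stretched matrix of the same size.
#' @export
cosine_stretch <- function(image, angle_deg) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (abs(angle_deg) >= 90) stop("|angle| must be < 90 degrees")
  ca <- cos(angle_deg * pi / 180)
  if (angle_deg == 0) return(image)
  n <- ncol(image); m <- nrow(image)
  centre <- (n + 1) / 2
  # content at offset c from centre maps to offset c / cos(a): sample input
  # at the contracted coordinate
  xs <- centre + (seq_len(n) - centre) * ca
  x0 <- floor(xs); fx <- xs - x0
  c0 <- pmin(pmax(x0, 1), n); c1 <- pmin(pmax(x0 + 1, 1), n)
  image[, c0, drop = FALSE] * rep(1 - fx, each = m) +
    image[, c1, drop = FALSE] * rep(fx, each = m)
}

## -- sub-pixel phase correlation ------------------------------------------

# Displacement d of image `mov` relative to `ref` (mov ~ content of ref
# moved by +d), estimated by phase correlation with local DFT upsampling
# (Guizar-Sicairos style). Returns c(d0 = columns, d1 = rows).
phase_corr_shift <- function(ref, mov, upsample = 10) {
  m <- nrow(ref); n <- ncol(ref)
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    warning("flat (zero-variance) image in cross-correlation; zero shift assumed")
    return(c(0, 0))
  }
  Fr <- stats::fft(ref); Fm <- stats::fft(mov)
  Xp <- Fr * Conj(Fm)
  # spectral whitening with a relative magnitude floor: frequencies whose
  # cross-power is below 5% of the peak carry no reliable phase (smooth,
  # low-texture images) and are damped instead of amplified
  Xp <- Xp / pmax(Mod(Xp), 0.05 * max(Mod(Xp)))
  cc <- Re(stats::fft(Xp, inverse = TRUE)) / length(Xp)
  pk <- which.max(cc)
  pr <- (pk - 1) %% m; pc <- (pk - 1) %/% m
  # wrap to signed offsets; correlation peak sits at -d (mod size)
  if (pr > m / 2) pr <- pr - m
  if (pc > n / 2) pc <- pc - n
  d1 <- -pr; d0 <- -pc
  if (upsample > 1) {
    # refine within +-1.5 px on an upsampled grid via explicit DFT
    off <- seq(-1.5, 1.5, by = 1 / upsample)
    kr <- c(0:floor((m - 1) / 2), -(ceiling((m - 1) / 2):1)) # fft frequencies
    kc <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    # cc(x) = sum_k Xp_k exp(+2*pi*i k x / size); peak near x = -d
    Er <- exp(2i * pi * outer(-d1 + off, kr) / m)
    Ec <- exp(2i * pi * outer(kc, -d0 + off) / n)
    cc_up <- Re(Er %*% Xp %*% Ec)
    pk <- arrayInd(which.max(cc_up), dim(cc_up))
    d1 <- d1 - off[pk[1]]
    d0 <- d0 - off[pk[2]]
  }
  c(d0, d1)
}

#' Coarse pre-alignment by cross-correlation of successive projections
#'
#' Estimates the translational displacement between cosine-stretched
#' successive projection images by sub-pixel phase correlation and
#' accumulates the pairwise offsets outward from the projection nearest
#' 0 degrees in both angular directions. Horizontal offsets are
#' accumulated in stretched (object) coordinates and converted back to
#' detector pixels with each image's own cosine; the reference image
#' defines the (unrecoverable) global position.
#'
#' @param b a [tilt_series()].
#' @param upsample sub-pixel upsampling factor of the correlation peak
#'   (default 10).
#' @return a [shift_set()]: estimated displacement of every image relative
#'   to the aligned chain (zero at the reference image). Warping `b` by the
#'   negated result registers the stack.
#' @export
prealign_crosscorr <- function(b, upsample = 10) {
  stopifnot(inherits(b, "tilt_series"))
  ang <- b$angles_deg
  na <- length(ang)
  i_ref <- which.min(abs(ang))
  stretched <- lapply(seq_len(na), function(i)
    cosine_stretch(b$images[, , i], ang[i]))
  # pairwise displacement of image i relative to image i-1, in stretched coords
  disp0 <- numeric(na); disp1 <- numeric(na) # cumulative, stretched frame
  walk <- function(idx_seq) {
    acc0 <- 0; acc1 <- 0
    prev <- i_ref
    for (i in idx_seq) {
      d <- phase_corr_shift(stretched[[prev]], stretched[[i]], upsample)
      acc0 <- acc0 + d[1]; acc1 <- acc1 + d[2]
      disp0[i] <<- acc0; disp1[i] <<- acc1
      prev <- i
    }
  }
  if (i_ref < na) walk((i_ref + 1):na)
  if (i_ref > 1) walk((i_ref - 1):1)
  f0 <- disp0 * cos(ang * pi / 180) # back to unstretched detector pixels
  shift_set(rbind(f0, disp1))
}
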