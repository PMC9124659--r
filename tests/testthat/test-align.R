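test_that("mask band follows the cosine law", {
  # 0 degrees, no margin: everything is inside
  g <- tilt_geometry(0, c(16, 16, 16))
  expect_equal(build_mask(g, margin_px = 0)[, , 1], matrix(1, 16, 16))

  # 60 degrees, n = 100: half-width 100/2 * cos(60) = 25 px exactly
  g <- tilt_geometry(c(0, 60), c(100, 100, 100))
  mk <- build_mask(g, margin_px = 0)
  cols_in <- which(colSums(mk[, , 2]) > 0)
  expect_equal(length(cols_in), 50) # band width 2 * 25 px
  expect_equal(min(cols_in) - 1, 100 - max(cols_in)) # centred
  expect_equal(sum(mk[, , 1]), 100 * 100)

  # row margin applies along the tilt axis
  mk2 <- build_mask(tilt_geometry(0, c(20, 20, 20)), margin_px = 2)
  expect_equal(unname(rowSums(mk2[, , 1]) > 0),
               c(FALSE, FALSE, rep(TRUE, 16), FALSE, FALSE))

  # per-angle support is non-increasing in |angle|
  g <- tilt_geometry(seq(0, 60, by = 5), c(64, 64, 64))
  mk <- build_mask(g, margin_px = 0)
  supp <- apply(mk, 3, sum)
  expect_true(all(diff(supp) <= 0))

  expect_error(build_mask(tilt_geometry(c(0, 89.9), c(16, 16, 16)), 4),
               "band width")
})

test_that("shift update is a fixed point at zero residual", {
  size <- 24
  geom <- tilt_geometry(c(-30, 0, 25), rep(size, 3))
  u <- make_phantom(phantom_spec(size = size, n_shapes = 4, seed = 5))
  b <- forward_project(u, geom)
  mask <- build_mask(geom, 2)

  f0 <- shift_set_zero(3)
  expect_equal(shift_update(u, b, f0, mask, geom), f0, tolerance = 1e-12)

  # integer current shifts: warping back reproduces A u exactly on the
  # masked interior, so the update must again return f_i
  f_int <- shift_set(matrix(c(1, -2, 0, 2, -1, 1), 2))
  b_shifted <- tilt_series(warp_stack(b$images, -f_int), geom$angles_deg)
  f_new <- shift_update(u, b_shifted, f_int, mask, geom)
  expect_equal(f_new, f_int, tolerance = 1e-10)
})

test_that("shift update solves the ramp problem in closed form", {
  size <- 16
  geom <- tilt_geometry(0, rep(size, 3))
  mask <- build_mask(geom, 2)
  ramp <- matrix(rep(seq_len(size), each = size), size) # b(r, c) = c
  delta <- 0.37
  b <- tilt_series(array(ramp - delta, c(size, size, 1)), 0) # ramp moved +delta
  u <- array(rep(ramp / size, size), c(size, size, size))    # A u = ramp
  expect_warning(
    f_new <- shift_update(u, b, shift_set_zero(1), mask, geom),
    "rank-deficient")
  expect_equal(unname(f_new[1, 1]), -delta, tolerance = 1e-10)
  expect_equal(unname(f_new[2, 1]), 0) # unidentifiable direction: previous kept
})

test_that("shift update matches a dense grid search of the objective", {
  # random single-angle problem; oracle: evaluate the linearized masked
  # objective on a 0.01 px grid over [-2, 2]^2 and take the argmin
  set.seed(13)
  size <- 16
  geom <- tilt_geometry(0, rep(size, 3))
  mask <- build_mask(geom, 2)
  blob <- function(shift = c(0, 0))
    gauss_image_shifted(size, size, 3, c(9.2, 7.7), shift) +
      0.5 * gauss_image_shifted(size, size, 2.2, c(5.5, 11.3), shift)
  u <- array(rep(blob() / size, size), rep(size, 3)) # A u = unshifted image
  delta <- c(0.45, -0.3)
  b <- tilt_series(array(blob(delta), c(size, size, 1)), 0)
  f_i <- shift_set(c(0.2, -0.1))

  f_hat <- shift_update(u, b, f_i, mask, geom)

  Au <- forward_project(u, geom)$images
  b_f <- warp_stack(b$images, f_i)
  G <- central_gradient(b_f)
  e <- as.numeric(Au - b_f)
  g0 <- as.numeric(G[, , , 1]); g1 <- as.numeric(G[, , , 2])
  mk <- as.numeric(mask)
  grid <- seq(-2, 2, by = 0.01)
  best <- c(NA, NA); best_val <- Inf
  # vectorized over df0 for each df1
  base <- outer(e, rep(1, length(grid))) +
    outer(g0, grid - f_i[1, 1])
  for (j in seq_along(grid)) {
    res <- base + g1 * (grid[j] - f_i[2, 1])
    vals <- colSums(mk * res^2)
    k <- which.min(vals)
    if (vals[k] < best_val) { best_val <- vals[k]; best <- c(grid[k], grid[j]) }
  }
  expect_lt(max(abs(c(f_hat[1, 1], f_hat[2, 1]) - best)), 0.02)
})

test_that("shift update is separable and translation-equivariant", {
  ds <- small_dataset(size = 24, step = 20, seed = 21)
  geom <- ds$geom
  mask <- build_mask(geom, 4)
  u <- ds$u_gt * 0.9
  f_i <- shift_set(matrix(runif(2 * length(geom$angles_deg), -0.5, 0.5), 2))
  f_new <- shift_update(u, ds$b, f_i, mask, geom)

  # per-angle separability: perturbing every other angle's image leaves
  # angle 1's update untouched
  imgs2 <- ds$b$images
  imgs2[, , -1] <- imgs2[, , -1] + rnorm(length(imgs2[, , -1]))
  f_new2 <- shift_update(u, tilt_series(imgs2, geom$angles_deg), f_i,
                         mask, geom)
  expect_equal(f_new2[, 1], f_new[, 1], tolerance = 1e-12)

  # equivariance: translating the data by an integer vector while moving
  # the warp correction the opposite way leaves the aligned stack -- and
  # hence the update increment -- unchanged on the mask interior
  t_int <- c(2, -1)
  b_t <- warp_stack(ds$b, shift_set(matrix(t_int, 2, ncol(f_i))))
  f_i_t <- shift_set(unclass(f_i) - t_int)
  f_new_t <- shift_update(u, b_t, f_i_t, mask, geom)
  expect_equal(unclass(f_new_t) - unclass(f_i_t),
               unclass(f_new) - unclass(f_i), tolerance = 1e-10)
})
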