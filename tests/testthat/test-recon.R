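test_that("grad3d/div3d are an exact adjoint pair", {
  expect_equal(grad3d(array(2.5, c(5, 6, 4))), array(0, c(5, 6, 4, 3)))

  # u(r, c, k) = c: column component 1 except last column, others 0
  u <- array(rep(rep(seq_len(6), each = 5), 4), c(5, 6, 4))
  g <- grad3d(u)
  expect_equal(g[, 1:5, , 2], array(1, c(5, 5, 4)))
  expect_equal(g[, 6, , 2], array(0, c(5, 4)))
  expect_equal(g[, , , 1], array(0, c(5, 6, 4)))

  set.seed(3)
  u <- array(rnorm(6^3), c(6, 6, 6))
  p <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  expect_equal(sum(grad3d(u) * p), -sum(u * div3d(p)), tolerance = 1e-12)

  expect_equal(div3d(array(0, c(6, 6, 6, 3))), array(0, c(6, 6, 6)))
  # constant field: zero divergence in the interior
  dv <- div3d(array(1, c(6, 6, 6, 3)))
  expect_equal(dv[2:5, 2:5, 2:5], array(0, c(4, 4, 4)))
})

test_that("proximal maps match numeric minimizers", {
  expect_equal(prox_data_dual(0, 0.7), 0)
  expect_equal(prox_data_dual(2, 1), 1)

  # argmin_q 0.5 (q - qt)^2 + sigma * 0.5 q^2: root of the optimality
  # condition, located numerically
  set.seed(11)
  for (j in 1:5) {
    qt <- rnorm(1, sd = 3); sg <- runif(1, 0.1, 4)
    oracle <- stats::uniroot(function(q) (q - qt) + sg * q, c(-20, 20),
                             tol = 1e-14)$root
    expect_equal(prox_data_dual(qt, sg), oracle, tolerance = 1e-9)
  }

  # ball projection: interior points fixed, boundary radial
  lam <- 0.8
  p_in <- array(c(0.1, -0.2, 0.15), c(1, 1, 1, 3))
  expect_equal(proj_l2inf_ball(p_in, lam), p_in)
  p_out <- array(c(2 * lam, 0, 0), c(1, 1, 1, 3))
  expect_equal(as.numeric(proj_l2inf_ball(p_out, lam)), c(lam, 0, 0))

  # oracle: solve the KKT condition p = v / (1 + mu), ||p|| = lam by
  # root finding, independent of the projection formula
  for (j in 1:5) {
    v <- rnorm(3, sd = 2)
    oracle <- if (sqrt(sum(v^2)) <= lam) v else {
      mu <- stats::uniroot(function(mu) sqrt(sum((v / (1 + mu))^2)) - lam,
                           c(0, 1e6), tol = 1e-14)$root
      v / (1 + mu)
    }
    got <- as.numeric(proj_l2inf_ball(array(v, c(1, 1, 1, 3)), lam))
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("preconditioners: closed-form sums and positivity", {
  # single 0-degree angle, unit weights: data row sums are the depth z
  z <- 12
  g <- tilt_geometry(0, c(8, 8, z))
  mask <- build_mask(g, 0)
  pre <- init_preconditioners(g, mask)
  expect_equal(pre$sigma_q, array(1 / z, c(8, 8, 1)))

  # interior voxel: gradient column sum 6, data column sum 1 -> tau = 1/7
  expect_equal(pre$tau[4, 4, 6], 1 / 7)
  # interior TV dual rows sum to 2
  expect_equal(pre$sigma_p[4, 4, 6, ], rep(1 / 2, 3))
  # Neumann far-edge rows are floored, not infinite
  expect_true(all(is.finite(pre$sigma_p)) && all(pre$sigma_p > 0))

  # default-style geometry: all steps strictly positive and finite
  g2 <- tilt_geometry(seq(-60, 60, by = 2), c(64, 64, 64))
  pre2 <- init_preconditioners(g2, build_mask(g2, 2))
  for (x in pre2) expect_true(all(is.finite(x)) && all(x > 0))
})

test_that("pd_iteration: fixed point at a consistent constant state", {
  g <- tilt_geometry(c(-20, 0, 30), c(12, 12, 12))
  mask <- build_mask(g, 2)
  cfg <- flara_config(lambda = 0.1, n_iter = 1)
  st <- pd_state_init(g, mask, cfg)
  u_true <- array(0.7, c(12, 12, 12))
  st$u <- u_true; st$u_bar <- u_true
  b_f <- forward_project(u_true, g)
  st2 <- pd_iteration(st, b_f, mask, g, cfg)
  expect_equal(st2$u, u_true, tolerance = 1e-12)
  expect_equal(st2$q, st$q, tolerance = 1e-12)
  expect_equal(st2$p, st$p, tolerance = 1e-12)
})

test_that("dual variable p stays inside the TV ball", {
  ds <- small_dataset(size = 16, step = 15, seed = 2)
  cfg <- flara_config(lambda = 0.05, n_iter = 1)
  mask <- build_mask(ds$geom, 2)
  st <- pd_state_init(ds$geom, mask, cfg)
  for (it in 1:25) {
    st <- pd_iteration(st, ds$clean, mask, ds$geom, cfg)
    pm <- matrix(st$p, ncol = 3)
    expect_lte(max(sqrt(rowSums(pm^2))), cfg$lambda * (1 + 1e-12))
  }
})

test_that("vanishing TV weight recovers the masked least-squares solution", {
  # dense oracle: build A explicitly, solve the masked normal equations
  size <- 8
  g <- tilt_geometry(seq(-80, 80, by = 10), rep(size, 3))
  mask <- build_mask(g, 0)
  nvox <- size^3
  A <- matrix(0, length(mask), nvox)
  for (j in seq_len(nvox)) {
    ej <- numeric(nvox); ej[j] <- 1
    A[, j] <- as.numeric(forward_project(array(ej, rep(size, 3)), g)$images)
  }
  A <- A * as.numeric(mask)
  u_true <- make_phantom(phantom_spec(size = size * 2, seed = 4,
                                      n_shapes = 3))[1:8, 1:8, 1:8] +
    ball_volume(size, 2.5)
  b <- as.numeric(mask) * as.numeric(forward_project(u_true, g)$images)
  AtA <- crossprod(A)
  expect_lt(kappa(AtA, exact = FALSE), 1e8) # oracle solution is unique
  u_star <- solve(AtA, crossprod(A, b))

  cfg <- flara_config(lambda = 1e-9, n_iter = 1)
  st <- pd_state_init(g, mask, cfg)
  bf <- array(b, dim(mask))
  for (it in 1:4000) st <- pd_iteration(st, bf, mask, g, cfg)
  rel <- sqrt(sum((as.numeric(st$u) - u_star)^2)) / sqrt(sum(u_star^2))
  expect_lt(rel, 1e-3)
})

test_that("primal energy settles and is monotone after burn-in", {
  ds <- small_dataset(size = 16, step = 10, seed = 6, shift_sigma = 0)
  cfg <- flara_config(lambda = 0.05, n_iter = 1)
  mask <- build_mask(ds$geom, 2)
  st <- pd_state_init(ds$geom, mask, cfg)
  energies <- c()
  for (it in 1:200) {
    st <- pd_iteration(st, ds$clean, mask, ds$geom, cfg)
    if (it >= 20 && it %% 10 == 0)
      energies <- c(energies, primal_energy(st$u, ds$clean, mask, ds$geom,
                                            cfg$lambda))
  }
  # non-increasing up to a tiny numerical slack
  expect_true(all(diff(energies) <= 1e-9 + 1e-6 * abs(energies[-1])))
})

test_that("energy converges and TV decreases with lambda", {
  ds <- small_dataset(size = 16, step = 10, seed = 9, shift_sigma = 0)
  mask <- build_mask(ds$geom, 2)
  tv <- function(u) {
    gm <- matrix(grad3d(u), ncol = 3)
    sum(sqrt(rowSums(gm^2)))
  }
  run <- function(lambda, iters) {
    cfg <- flara_config(lambda = lambda, n_iter = 1)
    st <- pd_state_init(ds$geom, mask, cfg)
    en <- c()
    for (it in seq_len(iters)) {
      st <- pd_iteration(st, ds$clean, mask, ds$geom, cfg)
      if (it %in% c(iters / 2, iters))
        en <- c(en, primal_energy(st$u, ds$clean, mask, ds$geom, lambda))
    }
    list(u = st$u, en = en)
  }
  # fixed-f energy at iteration 1000 within 0.1% of iteration 2000
  r <- run(0.05, 2000)
  expect_lt(abs(r$en[1] - r$en[2]) / abs(r$en[2]), 1e-3)

  tvs <- sapply(c(0.01, 0.1, 1), function(l) tv(run(l, 600)$u))
  expect_true(all(diff(tvs) < 0))
})
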