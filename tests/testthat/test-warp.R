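test_that("warp_stack: identity, integer re-indexing, sub-pixel ramps", {
  set.seed(2)
  b <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  expect_identical(warp_stack(b, shift_set_zero(3)), b)

  # integer shift moves a delta exactly (+f0 columns, +f1 rows)
  img <- array(0, c(11, 11, 1)); img[6, 6, 1] <- 1
  out <- warp_stack(img, shift_set(c(2, -3)))
  expect_equal(out[3, 8, 1], 1)
  expect_equal(sum(out), 1)

  # half-pixel shift of a linear ramp is the ramp evaluated at offset
  # coordinates in the interior
  ramp <- array(rep(seq_len(10), each = 10), c(10, 10, 1))
  out <- warp_stack(ramp, shift_set(c(0.5, 0)))
  expect_equal(out[, 3:10, 1],
               ramp[, 3:10, 1] - 0.5, tolerance = 1e-12)

  expect_error(warp_stack(b, matrix(c(NA, 0, 0, 0, 0, 0), 2)), "finite")
})

test_that("warp round trip is the identity away from the boundary", {
  m <- 32; n <- 32
  img <- array(gauss_image(m, n, sigma = 5), c(m, n, 1))
  set.seed(9)
  for (mag in c(0.7, 1.8, 3)) {
    dir <- runif(2, -1, 1); f <- mag * dir / sqrt(sum(dir^2))
    roundtrip <- warp_stack(warp_stack(img, shift_set(f)), shift_set(-f))
    interior <- 5:28
    expect_lt(max(abs(roundtrip[interior, interior, 1] -
                      img[interior, interior, 1])), 0.025)
  }
})

test_that("central_gradient matches the stencil oracle and annihilates affines", {
  expect_equal(central_gradient(array(3, c(7, 7, 2))),
               array(0, c(7, 7, 2, 2)))

  # affine image: exact gradient in the interior
  aff <- array(outer(seq_len(9), seq_len(9),
                     function(r, c) 2 * c - 0.5 * r), c(9, 9, 1))
  g <- central_gradient(aff)
  expect_equal(g[2:8, 2:8, 1, 1], matrix(2, 7, 7))
  expect_equal(g[2:8, 2:8, 1, 2], matrix(-0.5, 7, 7))

  # brute-force centred/one-sided differences on a random image
  set.seed(4)
  img <- matrix(rnorm(81), 9, 9)
  g <- central_gradient(array(img, c(9, 9, 1)))
  oracle0 <- matrix(0, 9, 9); oracle1 <- matrix(0, 9, 9)
  for (r in 1:9) for (c in 1:9) {
    cl <- max(c - 1, 1); cr <- min(c + 1, 9)
    rl <- max(r - 1, 1); rr <- min(r + 1, 9)
    oracle0[r, c] <- (img[r, cr] - img[r, cl]) / (cr - cl)
    oracle1[r, c] <- (img[rr, c] - img[rl, c]) / (rr - rl)
  }
  expect_equal(g[, , 1, 1], oracle0, tolerance = 1e-14)
  expect_equal(g[, , 1, 2], oracle1, tolerance = 1e-14)
})

test_that("linearized warp: zero increment, ramp exactness, quadratic order", {
  set.seed(6)
  b <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  f_i <- shift_set(matrix(runif(4, -1, 1), 2))
  expect_equal(linearized_warp(b, f_i, f_i), warp_stack(b, f_i))

  # ramps: Taylor is exact for any step
  ramp <- array(rep(seq_len(12), each = 12), c(12, 12, 1))
  for (delta in c(0.3, 1.2, 2.5)) {
    lin <- linearized_warp(ramp, shift_set_zero(1), shift_set(c(delta, 0)))
    exact <- ramp - delta # closed form, interior
    expect_equal(lin[3:10, 4:9, 1], exact[3:10, 4:9, 1], tolerance = 1e-10)
  }

  # smooth blob: linearization error shrinks quadratically in the step
  m <- 33; sig <- 4; ctr <- c(17, 17)
  blob <- array(gauss_image(m, m, sig, ctr), c(m, m, 1))
  errs <- sapply(c(0.4, 0.2, 0.1), function(delta) {
    lin <- linearized_warp(blob, shift_set_zero(1),
                           shift_set(c(delta, -delta)))
    exact <- gauss_image_shifted(m, m, sig, ctr, c(delta, -delta))
    max(abs(lin[5:29, 5:29, 1] - exact[5:29, 5:29]))
  })
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("cosine stretch dilates perpendicular to the tilt axis", {
  img <- matrix(rnorm(15 * 15), 15, 15)
  expect_identical(cosine_stretch(img, 0), img)

  # 60 degrees doubles offsets from the centre column
  delta <- matrix(0, 15, 15); delta[8, 8 + 3] <- 1
  out <- cosine_stretch(delta, 60)
  expect_equal(which.max(out[8, ]), 8 + 6)

  # 45 degrees widens a band by sqrt(2) (mass is conserved per row)
  band <- matrix(0, 21, 21); band[, 9:13] <- 1
  out <- cosine_stretch(band, 45)
  expect_equal(sum(out[11, ]) / 5, sqrt(2), tolerance = 0.06)

  expect_error(cosine_stretch(img, 90), "< 90")
})

test_that("pre-alignment recovers a constructed shift chain", {
  # identical images at every angle: no shift detected
  base <- gauss_image(24, 24, 3.5) + 0.3 * gauss_image(24, 24, 2, c(8, 15))
  ident <- tilt_series(array(rep(base, 5), c(24, 24, 5)),
                       seq(-2, 2, by = 1))
  f <- prealign_crosscorr(ident)
  expect_lt(max(abs(f)), 0.05)

  # image i is image i-1 moved by (+1, 0): cumulative displacement i - i_ref
  n_img <- 7
  stack <- array(0, c(24, 24, n_img))
  for (i in seq_len(n_img))
    stack[, , i] <- gauss_image_shifted(24, 24, 3.5, c(12.5, 12.5),
                                        c(i - 4, 0)) +
      0.3 * gauss_image_shifted(24, 24, 2, c(8, 15), c(i - 4, 0))
  chain <- tilt_series(stack, seq(-3, 3, by = 1))
  f <- prealign_crosscorr(chain)
  expect_equal(f[1, ], (1:n_img) - 4, tolerance = 0.15)
  expect_lt(max(abs(f[2, ])), 0.15)

  # flat image: zero shift with a warning, not an error
  flat <- tilt_series(array(c(base, matrix(1, 24, 24)), c(24, 24, 2)),
                      c(0, 1))
  expect_warning(prealign_crosscorr(flat), "flat")
})

test_that("pre-alignment residuals are sub-pixel on a shifted phantom", {
  ds <- small_dataset(size = 32, step = 5, seed = 8)
  pre <- prealign_crosscorr(ds$b)
  e <- unclass(pre) - unclass(ds$f_true)
  e <- e - shift_gauge_component(shift_set(e), ds$geom$angles_deg)
  expect_lt(median(abs(e[1, ])), 1)
  expect_lt(median(abs(e[2, ])), 1)
})
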