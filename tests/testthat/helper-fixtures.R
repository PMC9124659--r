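# Shared fixtures: everything is generated in code at test time.

# small geometry: cubic volume with matching detector
tiny_geom <- function(size = 16, angles = c(-40, -10, 0, 20, 55)) {
  tilt_geometry(angles, c(size, size, size))
}

# centred 2D Gaussian blob, unit peak
gauss_image <- function(m, n, sigma = max(m, n) / 8,
                        centre = c((m + 1) / 2, (n + 1) / 2)) {
  r <- matrix(seq_len(m), m, n)
  c_ <- matrix(seq_len(n), m, n, byrow = TRUE)
  exp(-((r - centre[1])^2 + (c_ - centre[2])^2) / (2 * sigma^2))
}

# stack of smooth blobs at distinct positions
gauss_stack <- function(m, n, na, sigma = max(m, n) / 8, seed = 42) {
  imgs <- array(0, c(m, n, na))
  set.seed(seed)
  for (i in seq_len(na)) {
    ctr <- c((m + 1) / 2 + runif(1, -m / 8, m / 8),
             (n + 1) / 2 + runif(1, -n / 8, n / 8))
    imgs[, , i] <- gauss_image(m, n, sigma, ctr)
  }
  imgs
}

# analytic translation of a Gaussian blob (exact warp reference)
gauss_image_shifted <- function(m, n, sigma, centre, shift) {
  gauss_image(m, n, sigma, centre + c(shift[2], shift[1]))
}

# soft-edged centred ball volume (projection is rotation-invariant);
# the smooth edge keeps interpolation error well below the band checked
ball_volume <- function(size, radius, soft = 3) {
  ax <- seq_len(size) - (size + 1) / 2
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  array(pmin(pmax((radius - r) / soft + 0.5, 0), 1), rep(size, 3))
}

withr_local_dir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}

# small reproducible dataset for driver-level tests
small_dataset <- function(size = 32, step = 4, seed = 3, shift_sigma = 1) {
  spec <- phantom_spec(size = size, n_shapes = 6, seed = seed)
  geom <- tilt_geometry(seq(-60, 60, by = step), rep(size, 3))
  make_dataset(spec, geom, shift_sigma = shift_sigma, seed = seed + 100L)
}
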