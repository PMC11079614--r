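# shared fixture builders (everything generated in code, fixed seeds)

rand_field <- function(grid, nt = 1L, seed = 1L, sd = 1) {
  set.seed(seed)
  u <- array(rnorm(grid$nx * grid$ny * nt, sd = sd), dim = c(grid$nx, grid$ny, nt))
  v <- array(rnorm(grid$nx * grid$ny * nt, sd = sd), dim = c(grid$nx, grid$ny, nt))
  velocity_field(grid, seq_len(nt) - 1, u, v)
}

# band-limited periodic random field (content only below wavenumber k_keep)
bandlimited_field <- function(grid, k_keep, seed = 1L) {
  set.seed(seed)
  filt <- function() {
    m <- matrix(rnorm(grid$nx * grid$ny), grid$nx, grid$ny)
    kx <- fstflux:::fft_wavenumbers(grid$nx, grid$dx)
    ky <- fstflux:::fft_wavenumbers(grid$ny, grid$dy)
    K2 <- outer(kx^2, ky^2, `+`)
    mh <- fft(m)
    mh[K2 > k_keep^2] <- 0
    Re(fft(mh, inverse = TRUE)) / length(m)
  }
  velocity_field(grid, 0, array(filt(), c(grid$nx, grid$ny, 1)),
                 array(filt(), c(grid$nx, grid$ny, 1)))
}

# independent space-domain oracle: periodic convolution with an
# analytically sampled gaussian kernel (no FFT anywhere); the kernel is
# periodised by summing images so it matches the periodic-domain filter
direct_gaussian_filter <- function(m, dx, dy, L) {
  nx <- nrow(m); ny <- ncol(m)
  s2 <- L^2 / 12
  ox <- ((0:(nx - 1) + nx / 2) %% nx - nx / 2) * dx
  oy <- ((0:(ny - 1) + ny / 2) %% ny - ny / 2) * dy
  K <- matrix(0, nx, ny)
  for (mi in -2:2) for (mj in -2:2)
    K <- K + exp(-outer((ox + mi * nx * dx)^2, (oy + mj * ny * dy)^2, `+`) / (2 * s2))
  K <- K / sum(K)
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      shifted <- K[((seq_len(nx) - i) %% nx) + 1, ((seq_len(ny) - j) %% ny) + 1]
      out[i, j] <- sum(m * shifted)
    }
  }
  out
}

expect_field_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a$u - b$u)), tol)
  expect_lt(max(abs(a$v - b$v)), tol)
  expect_equal(a$times, b$times, tolerance = 1e-12)
}
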