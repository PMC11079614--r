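test_that("every kernel preserves a constant field and the domain mean (periodic)", {
  g <- grid2d(32, 32, 0.1)
  cval <- 1.7
  f <- velocity_field(g, 0, array(cval, c(32, 32, 1)), array(-0.4, c(32, 32, 1)))
  for (kernel in c("gaussian", "sharp", "tophat")) {
    for (padding in c("mirror", "periodic", "zero")) {
      # zero padding cannot preserve a constant near the boundary; skip it there
      if (padding == "zero") next
      spec <- filter_spec(0.8, kernel, padding)
      lp <- lowpass(f, spec)
      expect_lt(max(abs(lp$u - cval)), 1e-12,
                label = paste(kernel, padding, "constant preservation"))
    }
  }
  r <- rand_field(g, seed = 5)
  for (kernel in c("gaussian", "sharp", "tophat")) {
    spec <- filter_spec(0.9, kernel, "periodic")
    lp <- lowpass(r, spec)
    expect_lt(abs(mean(lp$u) - mean(r$u)), 1e-12)
    expect_lt(abs(mean(lp$v) - mean(r$v)), 1e-12)
  }
})

test_that("kernel transfer functions match their closed forms on sinusoids", {
  g <- grid2d(64, 64, 0.1)
  co <- grid_coords(g)
  for (mode in c(3, 7, 12)) {
    k <- 2 * pi * mode / (g$nx * g$dx)
    u <- array(sin(k * co$x), c(64, 64, 1))
    f <- velocity_field(g, 0, u, array(0, c(64, 64, 1)))
    L <- 1.2
    lp <- lowpass(f, filter_spec(L, "gaussian", "periodic"))
    H <- exp(-k^2 * (L^2 / 12) / 2)
    expect_lt(max(abs(lp$u - H * u)), 1e-8)
  }
  # sharp-spectral annihilates wavelengths below L ...
  k_small <- 2 * pi * 20 / (g$nx * g$dx)   # wavelength 0.32 cm
  f2 <- velocity_field(g, 0, array(sin(k_small * co$x), c(64, 64, 1)),
                       array(0, c(64, 64, 1)))
  lp2 <- lowpass(f2, filter_spec(2, "sharp", "periodic"))
  expect_lt(max(abs(lp2$u)), 1e-10)
  # ... and passes wavelengths above it untouched
  k_big <- 2 * pi * 1 / (g$nx * g$dx)
  f3 <- velocity_field(g, 0, array(sin(k_big * co$x), c(64, 64, 1)),
                       array(0, c(64, 64, 1)))
  lp3 <- lowpass(f3, filter_spec(2, "sharp", "periodic"))
  expect_lt(max(abs(lp3$u - f3$u)), 1e-10)
})

test_that("FFT filtering equals the direct space-domain convolution oracle", {
  g <- grid2d(32, 32, 0.1)
  f <- rand_field(g, seed = 11)
  L <- 1.0
  lp <- lowpass(f, filter_spec(L, "gaussian", "periodic"))
  oracle <- direct_gaussian_filter(f$u[, , 1], g$dx, g$dy, L)
  expect_lt(max(abs(lp$u[, , 1] - oracle)), 1e-10)
})

test_that("filtering is linear and residual + lowpass restores the field", {
  g <- grid2d(32, 32, 0.1)
  a <- rand_field(g, seed = 1); b <- rand_field(g, seed = 2)
  spec <- filter_spec(0.8, "gaussian", "mirror")
  comb <- velocity_field(g, 0, 2.5 * a$u - 1.3 * b$u, 2.5 * a$v - 1.3 * b$v)
  lhs <- lowpass(comb, spec)
  la <- lowpass(a, spec); lb <- lowpass(b, spec)
  expect_lt(max(abs(lhs$u - (2.5 * la$u - 1.3 * lb$u))), 1e-12)
  r <- residual(a, spec)
  expect_lt(max(abs(r$u + la$u - a$u)), 1e-13)
  expect_lt(max(abs(r$v + la$v - a$v)), 1e-13)
})

test_that("sharp-spectral filtering is a projector (residual of lowpass is zero)", {
  g <- grid2d(32, 32, 0.1)
  f <- rand_field(g, seed = 9)
  spec <- filter_spec(1.1, "sharp", "periodic")
  r <- residual(f, spec)
  rr <- lowpass(r, spec)
  expect_lt(max(abs(rr$u)), 1e-10)
  expect_lt(max(abs(rr$v)), 1e-10)
})

test_that("a symmetric kernel leaves a linear field unchanged in the interior", {
  g <- grid2d(48, 48, 0.1, x0 = -2.35, y0 = -2.35)
  co <- grid_coords(g)
  u <- array(outer(0.3 * co$x, 0.5 * co$y, `+`), c(48, 48, 1))
  f <- velocity_field(g, 0, u, -u)
  for (kernel in c("gaussian", "tophat")) {
    spec <- filter_spec(0.8, kernel, "mirror")
    lp <- lowpass(f, spec)
    # interior must clear the kernel's full support: the gaussian tail
    # reaches ~5 sigma = 1.5 L, so take a 2 L margin
    idx <- fstflux:::interior_indices(g, 2 * spec$L)
    expect_lt(max(abs(lp$u[idx$ix, idx$iy, 1] - u[idx$ix, idx$iy, 1])), 1e-8,
              label = kernel)
  }
})

test_that("filtered_product matches its definition and the gaussian moment identity", {
  g <- grid2d(32, 32, 0.1)
  spec <- filter_spec(0.8, "gaussian", "periodic")
  set.seed(20)
  for (rep in 1:5) {
    fa <- scalar_field(g, 0, array(rnorm(32 * 32), c(32, 32, 1)))
    fb <- scalar_field(g, 0, array(rnorm(32 * 32), c(32, 32, 1)))
    fp <- filtered_product(fa, fb, spec)
    direct <- fstflux:::filter_cube(fa$values * fb$values, g$dx, g$dy, spec)
    expect_lt(max(abs(fp$values - direct)), 1e-12)
  }
  # constant * constant
  ca <- scalar_field(g, 0, array(3, c(32, 32, 1)))
  expect_lt(max(abs(filtered_product(ca, ca, spec)$values - 9)), 1e-12)
  # for linear f, g: (fg)^L - f^L g^L = sigma^2 * (grad f . grad g)
  g2 <- grid2d(48, 48, 0.1, x0 = -2.35, y0 = -2.35)
  co <- grid_coords(g2)
  L <- 0.8; s2 <- L^2 / 12
  spec2 <- filter_spec(L, "gaussian", "mirror")
  fl <- scalar_field(g2, 0, array(outer(1.1 * co$x, 0.4 * co$y, `+`), c(48, 48, 1)))
  gl <- scalar_field(g2, 0, array(outer(-0.7 * co$x, 0.9 * co$y, `+`), c(48, 48, 1)))
  fp2 <- filtered_product(fl, gl, spec2)
  lf <- fstflux:::filter_cube(fl$values, g2$dx, g2$dy, spec2)
  lg <- fstflux:::filter_cube(gl$values, g2$dx, g2$dy, spec2)
  lhs <- fp2$values - lf * lg
  rhs <- s2 * (1.1 * (-0.7) + 0.4 * 0.9)
  idx <- fstflux:::interior_indices(g2, 2 * L)  # clear the gaussian tail
  expect_lt(max(abs(lhs[idx$ix, idx$iy, 1] - rhs)), 1e-8)
})

test_that("filter_sweep validates its scales and yields non-increasing energy (sharp)", {
  g <- grid2d(64, 64, 0.1)
  f <- rand_field(g, seed = 14)
  expect_identical(length(filter_sweep(f, numeric(0))), 0L)
  tmpl <- filter_spec(1, "sharp", "periodic")
  single <- filter_sweep(f, 1.5, tmpl)[[1]]
  expect_lt(max(abs(single$u - lowpass(f, filter_spec(1.5, "sharp", "periodic"))$u)), 1e-14)
  Ls <- c(0.5, 1, 2, 4)
  sw <- filter_sweep(f, Ls, tmpl)
  E <- vapply(sw, function(s) mean(s$u^2 + s$v^2) / 2, numeric(1))
  expect_true(all(diff(E) <= 1e-14))
  expect_error(filter_sweep(f, c(1, 0.5), tmpl), "increasing")
  expect_error(filter_sweep(f, c(0.05, 1), tmpl), "L")
  expect_error(lowpass(f, filter_spec(0.15, "gaussian")), "exceed")
})

test_that("masked nodes are excluded via normalised convolution", {
  g <- grid2d(32, 32, 0.1)
  cval <- 2.0
  u <- array(cval, c(32, 32, 1)); v <- array(0, c(32, 32, 1))
  mask <- array(TRUE, c(32, 32, 1))
  mask[14:18, 14:18, 1] <- FALSE
  u[!mask] <- 1e6   # garbage under the mask must not leak
  f <- velocity_field(g, 0, u, v, mask)
  lp <- lowpass(f, filter_spec(0.8, "gaussian", "mirror"))
  expect_lt(max(abs(lp$u[lp$mask] - cval)), 1e-9)
})
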