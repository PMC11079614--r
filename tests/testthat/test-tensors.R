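test_that("constant fields give vanishing stresses of every flavour", {
  g <- grid2d(32, 32, 0.1)
  f <- velocity_field(g, 0, array(2, c(32, 32, 1)), array(-1, c(32, 32, 1)))
  spec <- filter_spec(0.8, "gaussian", "mirror")
  expect_lt(max(abs(turbulent_stress(f, spec)$txx)), 1e-12)
  expect_lt(max(abs(sgs_reynolds_stress(f, spec)$tyy)), 1e-12)
  lc <- leonard_cross_stresses(f, spec)
  expect_lt(max(abs(lc$leonard$txy), abs(lc$cross$txx)), 1e-12)
  gd <- germano_decomposition(f, spec)
  expect_lt(max(abs(gd$leonard$txx), abs(gd$cross$txy), abs(gd$reynolds$tyy)), 1e-12)
})

test_that("pure-shear turbulent stress matches the gaussian second-moment closed form", {
  # v = gamma * x filtered with gaussian of variance s2: tau_yy = gamma^2 s2,
  # tau_xy = tau_xx = 0 in the interior
  g <- grid2d(101, 101, 0.07, x0 = -3.5, y0 = -3.5)
  gamma <- 2 * 1.2 / 7
  sh <- make_shear(shear_spec(gamma = gamma), g)
  L <- 1.0; s2 <- L^2 / 12
  spec <- filter_spec(L, "gaussian", "mirror")
  tau <- turbulent_stress(sh, spec)
  idx <- fstflux:::interior_indices(g, 2 * L)  # clear the gaussian tail
  expect_lt(max(abs(tau$tyy[idx$ix, idx$iy, 1] - gamma^2 * s2)) / (gamma^2 * s2), 1e-6)
  expect_lt(max(abs(tau$txy[idx$ix, idx$iy, 1])), 1e-12)
  expect_lt(max(abs(tau$txx[idx$ix, idx$iy, 1])), 1e-12)
})

test_that("turbulent stress agrees with the direct-convolution oracle", {
  g <- grid2d(32, 32, 0.1)
  f <- bandlimited_field(g, k_keep = 15, seed = 8)
  L <- 1.0
  spec <- filter_spec(L, "gaussian", "periodic")
  tau <- turbulent_stress(f, spec)
  u <- f$u[, , 1]; v <- f$v[, , 1]
  lu <- direct_gaussian_filter(u, g$dx, g$dy, L)
  lv <- direct_gaussian_filter(v, g$dx, g$dy, L)
  oxx <- direct_gaussian_filter(u * u, g$dx, g$dy, L) - lu * lu
  oxy <- direct_gaussian_filter(u * v, g$dx, g$dy, L) - lu * lv
  expect_lt(max(abs(tau$txx[, , 1] - oxx)), 1e-10)
  expect_lt(max(abs(tau$txy[, , 1] - oxy)), 1e-10)
})

test_that("subgrid Reynolds stress is positive semidefinite under the gaussian kernel", {
  g <- grid2d(48, 48, 0.1)
  for (seed in 1:3) {
    f <- rand_field(g, seed = seed)
    tS <- sgs_reynolds_stress(f, filter_spec(0.9, "gaussian", "mirror"))
    nrm <- sqrt(mean(tS$txx^2 + 2 * tS$txy^2 + tS$tyy^2))
    expect_gte(min(tS$txx), -1e-12 * nrm)
    expect_gte(min(tS$tyy), -1e-12 * nrm)
    expect_gte(min(tS$txx * tS$tyy - tS$txy^2), -1e-12 * nrm^2)
  }
})

test_that("below a sharp cutoff the residual is the whole field and tauS = tau", {
  g <- grid2d(64, 64, 0.1)
  L <- 1.0
  kc <- pi / L
  # field with all content strictly above kc (scales below L)
  set.seed(3)
  co <- grid_coords(g)
  k1 <- 2 * pi * 15 / (g$nx * g$dx); k2 <- 2 * pi * 21 / (g$nx * g$dx)
  stopifnot(k1 > kc, k2 > kc)
  u <- array(outer(sin(k1 * co$x), cos(k2 * co$y)), c(64, 64, 1))
  v <- array(outer(cos(k2 * co$x), sin(k1 * co$y)), c(64, 64, 1))
  f <- velocity_field(g, 0, u, v)
  spec <- filter_spec(L, "sharp", "periodic")
  tau <- turbulent_stress(f, spec)
  tS <- sgs_reynolds_stress(f, spec)
  expect_lt(max(abs(tau$txx - tS$txx)), 1e-10)
  expect_lt(max(abs(tau$txy - tS$txy)), 1e-10)
  lc <- leonard_cross_stresses(f, spec)
  expect_lt(max(abs(lc$leonard$txx)), 1e-10)
  expect_lt(max(abs(lc$cross$txy)), 1e-10)
})

test_that("tau = Leonard + cross + tauS and the Germano components sum to tau", {
  g <- grid2d(32, 32, 0.1)
  for (seed in c(2, 6)) {
    f <- rand_field(g, seed = seed)
    for (spec in list(filter_spec(0.8, "gaussian", "mirror"),
                      filter_spec(1.1, "tophat", "periodic"))) {
      tau <- turbulent_stress(f, spec)
      lc <- leonard_cross_stresses(f, spec)
      tS <- sgs_reynolds_stress(f, spec)
      for (cmp in c("txx", "txy", "tyy"))
        expect_lt(max(abs(tau[[cmp]] - lc$leonard[[cmp]] - lc$cross[[cmp]] - tS[[cmp]])),
                  1e-12)
      gd <- germano_decomposition(f, spec)
      for (cmp in c("txx", "txy", "tyy"))
        expect_lt(max(abs(tau[[cmp]] - gd$leonard[[cmp]] - gd$cross[[cmp]] - gd$reynolds[[cmp]])),
                  1e-12)
    }
  }
})

test_that("Germano components are Galilean invariant; the classical split is not", {
  g <- grid2d(32, 32, 0.1)
  f <- rand_field(g, seed = 4)
  f2 <- velocity_field(g, 0, f$u + 7.3, f$v - 2.1)
  spec <- filter_spec(0.8, "gaussian", "mirror")
  gd <- germano_decomposition(f, spec)
  gd2 <- germano_decomposition(f2, spec)
  for (part in c("leonard", "cross", "reynolds"))
    for (cmp in c("txx", "txy", "tyy"))
      expect_lt(max(abs(gd[[part]][[cmp]] - gd2[[part]][[cmp]])), 1e-10,
                label = paste("germano", part, cmp))
  lc <- leonard_cross_stresses(f, spec)
  lc2 <- leonard_cross_stresses(f2, spec)
  expect_gt(max(abs(lc$cross$txx - lc2$cross$txx)), 1e-3)
})

test_that("strain rate is exact for linear fields and vanishes for rigid rotation", {
  g <- grid2d(32, 32, 0.1, x0 = -1.55, y0 = -1.55)
  co <- grid_coords(g)
  gamma <- 0.7
  v <- array(rep(gamma * co$x, g$ny), c(32, 32, 1))
  f <- velocity_field(g, 0, array(0, c(32, 32, 1)), v)
  S <- strain_rate(f)
  expect_lt(max(abs(S$txy - gamma / 2)), 1e-13)
  expect_lt(max(abs(S$txx)), 1e-13)
  expect_lt(max(abs(S$tyy)), 1e-13)
  Om <- 0.4
  u2 <- array(outer(rep(-Om, g$nx), co$y), c(32, 32, 1))
  v2 <- array(matrix(Om * co$x, g$nx, g$ny), c(32, 32, 1))
  S2 <- strain_rate(velocity_field(g, 0, u2, v2))
  expect_lt(max(abs(S2$txx), abs(S2$txy), abs(S2$tyy)), 1e-12)
})

test_that("deviatoric removes the trace and leaves traceless tensors alone", {
  g <- grid2d(32, 32, 0.1)
  set.seed(12)
  mk <- function() array(rnorm(32 * 32), c(32, 32, 1))
  T <- tensor_field(g, 0, mk(), mk(), mk())
  D <- deviatoric(T)
  expect_lt(max(abs(D$txx + D$tyy)), 1e-14)
  D2 <- deviatoric(D)
  expect_lt(max(abs(D2$txx - D$txx)), 1e-14)
  I2 <- tensor_field(g, 0, array(1, c(32, 32, 1)), array(0, c(32, 32, 1)),
                     array(1, c(32, 32, 1)))
  DI <- deviatoric(I2)
  expect_lt(max(abs(DI$txx), abs(DI$txy), abs(DI$tyy)), 1e-15)
})

test_that("eigenframe recovers known orientations and is rotation equivariant", {
  g <- grid2d(4, 4, 0.1)
  one <- function(z) array(z, c(4, 4, 1))
  # pure positive shear -> extensional axis at pi/4
  S <- tensor_field(g, 0, one(0), one(0.35), one(0))
  ef <- eigenframe(S)
  expect_equal(unique(as.numeric(ef$angle)), pi / 4, tolerance = 1e-14)
  # diag(a, -a) -> angle 0, lambda a
  Sa <- tensor_field(g, 0, one(0.9), one(0), one(-0.9))
  efa <- eigenframe(Sa)
  expect_equal(unique(as.numeric(efa$angle)), 0, tolerance = 1e-14)
  expect_equal(unique(as.numeric(efa$lambda)), 0.9, tolerance = 1e-14)
  # rotation equivariance for 100 random deviatoric tensors
  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(1); b <- rnorm(1); phi <- runif(1, 0, pi)
    T0 <- tensor_field(g, 0, one(a), one(b), one(-a))
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    M <- R %*% matrix(c(a, b, b, -a), 2) %*% t(R)
    Tr <- tensor_field(g, 0, one(M[1, 1]), one(M[1, 2]), one(M[2, 2]))
    a0 <- eigenframe(T0)$angle[1, 1, 1]
    ar <- eigenframe(Tr)$angle[1, 1, 1]
    expect_lt(min(abs(((ar - a0 - phi) %% pi)), abs(((ar - a0 - phi) %% pi) - pi)), 1e-10)
  }
  # a degenerate (isotropic) tensor is flagged, not given a fake angle
  Tdeg <- tensor_field(g, 0, one(0), one(0), one(0))
  expect_true(all(is.na(eigenframe(Tdeg)$angle)))
})

test_that("solver output is incompressible: tr(S) is negligible", {
  cfg <- solver_config(n = 32, domain_size = 6.4, nu = 0.02, alpha = 0.05, dt = 0.01)
  st <- solver_init(cfg, noise_amplitude = 0.5)
  for (i in 1:20) st <- solver_step(st)
  f <- solver_velocity(st)
  S <- strain_rate(f, method = "spectral")
  rms <- sqrt(mean(S$txx^2 + 2 * S$txy^2 + S$tyy^2))
  expect_lt(max(abs(S$txx + S$tyy)), 1e-8 * rms)
})
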