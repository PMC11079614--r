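naive_contraction <- function(tau, S, i, j, k) {
  Tm <- matrix(c(tau$txx[i, j, k], tau$txy[i, j, k],
                 tau$txy[i, j, k], tau$tyy[i, j, k]), 2)
  Sm <- matrix(c(S$txx[i, j, k], S$txy[i, j, k],
                 S$txy[i, j, k], S$tyy[i, j, k]), 2)
  acc <- 0
  for (a in 1:2) for (b in 1:2) acc <- acc + Tm[a, b] * Sm[a, b]
  -acc
}

test_that("flux contraction matches a naive double-loop oracle and zero stress gives zero", {
  g <- grid2d(8, 8, 0.1)
  set.seed(17)
  mk <- function() array(rnorm(8 * 8), c(8, 8, 1))
  tau <- tensor_field(g, 0, mk(), mk(), mk(), attrs = list(kernel = "gaussian", L = 1))
  S <- tensor_field(g, 0, mk(), mk(), mk(), attrs = list(kernel = "gaussian", L = 1))
  Q <- flux_pointwise(tau, S)
  for (pick in 1:10) {
    i <- sample(8, 1); j <- sample(8, 1)
    expect_equal(Q$values[i, j, 1], naive_contraction(tau, S, i, j, 1),
                 tolerance = 1e-12)
  }
  zero <- tensor_field(g, 0, mk() * 0, mk() * 0, mk() * 0,
                       attrs = list(kernel = "gaussian", L = 1))
  expect_true(all(flux_pointwise(zero, S)$values == 0))
  # metadata guard
  S2 <- S; S2$attrs$L <- 2
  expect_error(flux_pointwise(tau, S2), "mismatch")
})

test_that("the tensor-geometry form reproduces the direct contraction (Eq.1 == Eq.2)", {
  set.seed(100)
  n <- 1000
  a1 <- rnorm(n); b1 <- rnorm(n); a2 <- rnorm(n); b2 <- rnorm(n)
  # deviatoric pairs [[a, b], [b, -a]]
  lam1 <- sqrt(a1^2 + b1^2); lam2 <- sqrt(a2^2 + b2^2)
  ang1 <- atan2(b1, a1) / 2; ang2 <- atan2(b2, a2) / 2
  theta <- fstflux:::fold_axial_angle(ang1 - ang2)
  q_geom <- flux_from_geometry(lam1, lam2, theta)
  q_direct <- -(a1 * a2 + 2 * b1 * b2 + a1 * a2)
  expect_lt(max(abs(q_geom - q_direct)), 1e-12)
})

test_that("geometric flux vanishes exactly at pi/4 and nowhere else", {
  expect_identical(flux_from_geometry(1, 1, pi / 4), 0)
  thetas <- setdiff(seq(0, pi / 2, length.out = 91), pi / 4)
  q <- flux_from_geometry(1, 1, thetas)
  expect_true(all(q[thetas < pi / 4] < 0))
  expect_true(all(q[thetas > pi / 4] > 0))
  expect_equal(flux_from_geometry(1, 1, 0), -2)
  expect_equal(flux_from_geometry(1, 1, pi / 2), 2)
  # monotone efficiency at fixed eigenvalues
  expect_true(all(diff(q) > 0))
  expect_error(flux_from_geometry(-1, 1, 0), "non-negative")
  expect_error(flux_from_geometry(1, 1, 2), "theta")
})

test_that("alignment_angle recovers imposed alignments and closes the loop with Eq. 2", {
  g <- grid2d(8, 8, 0.1)
  one <- function(z) array(z, c(8, 8, 1))
  meta <- list(kernel = "gaussian", L = 1)
  S <- tensor_field(g, 0, one(0.2), one(0.5), one(-0.2), attrs = meta)
  # tau = S -> theta = 0
  ga <- alignment_angle(S, S)
  expect_lt(max(abs(ga$theta)), 1e-12)
  # tau rotated by pi/2 -> theta = pi/2 (deviatoric sign flip)
  Tr <- tensor_field(g, 0, one(-0.2), one(-0.5), one(0.2), attrs = meta)
  gr <- alignment_angle(Tr, S)
  expect_lt(max(abs(gr$theta - pi / 2)), 1e-12)
  # end-to-end identity on solver output: Eq. 2 from the geometry equals
  # the direct deviatoric contraction nodewise
  cfg <- solver_config(n = 32, domain_size = 6.4, nu = 0.02, alpha = 0.05, dt = 0.01)
  st <- solver_init(cfg, noise_amplitude = 0.5)
  for (i in 1:30) st <- solver_step(st)
  f <- solver_velocity(st)
  spec <- filter_spec(0.8, "gaussian", "periodic")
  tau <- turbulent_stress(f, spec)
  Sf <- strain_rate(lowpass(f, spec), method = "spectral")
  geo <- alignment_angle(tau, Sf)
  q_geom <- flux_from_geometry(geo$lambda_tau, geo$lambda_S, geo$theta)
  dtau <- deviatoric(tau); dS <- deviatoric(Sf)
  q_direct <- -(dtau$txx * dS$txx + 2 * dtau$txy * dS$txy + dtau$tyy * dS$tyy)
  ok <- !is.na(geo$theta)
  scale <- max(abs(q_direct))
  expect_lt(max(abs(q_geom[ok] - q_direct[ok])), 1e-10 * max(1, scale))
})

test_that("laminar pure shear has negligible interior flux at every cutoff", {
  g <- grid2d(101, 101, 0.07, x0 = -3.5, y0 = -3.5)
  gamma <- 2 * 1.2 / 7
  sh <- make_shear(shear_spec(gamma = gamma), g)
  curve <- net_flux_curve(sh, c(0.5, 1, 2, 3), filter_spec(1, "gaussian", "mirror"))
  # scale: gamma^3 sigma^2 at the largest L
  scale <- gamma^3 * (3^2 / 12)
  expect_true(all(abs(curve$mean) < 1e-8 * scale))
})

test_that("swimmer scenarios give the predicted flux signs and a jet-localised Qs map", {
  g <- grid2d(81, 81, 0.1, x0 = -4, y0 = -4)
  sh <- shear_spec(v_max = 1.2, W = 7)
  tmpl <- filter_spec(1, "gaussian", "mirror")
  # cutoffs above the wake's agitation scale (~3 cm) and below the shear width
  mean_flux <- function(theta) {
    ev <- swimmer_event(position = c(0, 0), theta_s = theta, shear = sh)
    f <- swimmer_field(ev, sh, g, times = 0)
    net_flux_curve(f, c(3, 3.5, 4, 4.5), tmpl)$mean
  }
  q0 <- mean_flux(0); q90 <- mean_flux(pi / 2)
  expect_true(all(q0 < 0))          # aligned: inverse flux
  expect_true(all(q90 > 0))         # anti-aligned: forward flux
  # Qs map at L = 4 cm is maximal near the swimmer
  ev <- swimmer_event(position = c(0, 0), theta_s = 0, shear = sh)
  f <- swimmer_field(ev, sh, g, times = 0)
  spec4 <- filter_spec(4, "gaussian", "mirror")
  q <- sgs_flux_pointwise(sgs_reynolds_stress(f, spec4),
                          strain_rate(lowpass(f, spec4)))
  idx <- fstflux:::interior_indices(g, 2)
  sub <- abs(q$values[idx$ix, idx$iy, 1])
  peak <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  co <- grid_coords(g)
  expect_lt(abs(co$x[idx$ix[peak[1]]]), 2)
  expect_lt(abs(co$y[idx$iy[peak[2]]]), 2.5)
})

test_that("theta_s classification matches the shear eigenframe geometry", {
  # direction along the extensional eigenvector (pi/4) -> aligned, theta_s = 0
  r <- classify_theta_s(c(1, 1), pi / 4)
  expect_equal(r$theta_s, 0)
  expect_identical(r$category, "aligned")
  r2 <- classify_theta_s(c(1, 0), pi / 4)
  expect_equal(r2$theta_s, pi / 4, tolerance = 1e-12)
  expect_identical(r2$category, "neutral")
  r3 <- classify_theta_s(c(-1, 1), pi / 4)
  expect_equal(r3$theta_s, pi / 2, tolerance = 1e-12)
  expect_identical(r3$category, "anti_aligned")
  expect_error(classify_theta_s(c(0, 0), pi / 4), "zero-length")
})

test_that("effective viscosity carries the flux sign and masks strain-free nodes", {
  g <- grid2d(8, 8, 0.1)
  one <- function(z) array(z, c(8, 8, 1))
  S <- tensor_field(g, 0, one(0), one(0.5), one(0))
  Qpos <- scalar_field(g, 0, one(1)); Qneg <- scalar_field(g, 0, one(-1))
  expect_true(all(effective_viscosity(Qpos, S)$values > 0))
  expect_true(all(effective_viscosity(Qneg, S)$values < 0))
  Q0 <- scalar_field(g, 0, one(0))
  expect_true(all(effective_viscosity(Q0, S)$values == 0))
  # nu_e = Q / (2 SijSij) quantitatively
  expect_equal(effective_viscosity(Qpos, S)$values[1, 1, 1], 1 / (2 * 2 * 0.25))
})
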