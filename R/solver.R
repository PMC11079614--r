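#' Configuration for the quasi-2D pseudo-spectral solver
#'
#' Doubly periodic vorticity–streamfunction solver with 2/3-rule
#' dealiasing. Viscosity and the linear (Rayleigh) friction `alpha` — the
#' large-scale energy sink of quasi-2D laboratory layers, whose
#' dissipation rate is proportional to the kinetic energy — are integrated
#' exactly with an integrating factor; the nonlinear term and forcing use
#' classical RK4.
#'
#' @param n Modes per side; a power of two, at least 32.
#' @param domain_size Periodic box size in cm.
#' @param nu Kinematic viscosity (cm^2/s), >= 0.
#' @param alpha Linear-friction rate (1/s), >= 0.
#' @param dt Time step (s).
#' @param seed Integer seed (initial perturbation, schedules).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n = 64L, domain_size = 12, nu = 0.05, alpha = 0.3,
                          dt = 0.015, seed = 1L) {
  n <- as.integer(n)
  if (n < 32L || bitwAnd(n, n - 1L) != 0L)
    stop("solver_config: n must be a power of two >= 32")
  if (nu < 0 || alpha < 0) stop("solver_config: nu and alpha must be >= 0")
  if (!(dt > 0) || !(domain_size > 0))
    stop("solver_config: dt and domain_size must be positive")
  structure(list(n = n, domain_size = domain_size, nu = nu, alpha = alpha,
                 dt = dt, seed = as.integer(seed)),
            class = "solver_config")
}

solver_operators <- function(config) {
  n <- config$n; D <- config$domain_size
  k <- fft_wavenumbers(n, D / n)
  KX <- matrix(k, n, n); KY <- matrix(k, n, n, byrow = TRUE)
  K2 <- KX^2 + KY^2
  K2inv <- 1 / K2; K2inv[1, 1] <- 0
  kmax <- max(abs(k))
  dealias <- (abs(KX) <= (2 / 3) * kmax) & (abs(KY) <= (2 / 3) * kmax)
  list(KX = KX, KY = KY, K2 = K2, K2inv = K2inv, dealias = dealias,
       decay = config$nu * K2 + config$alpha)
}

solver_velocity_hat <- function(wh, ops) {
  psih <- wh * ops$K2inv
  list(uh = 1i * ops$KY * psih, vh = -1i * ops$KX * psih)
}

ifft_re <- function(zh) Re(stats::fft(zh, inverse = TRUE)) / length(zh)

# dealiased nonlinear tendency N(w) = -(u dw/dx + v dw/dy), spectral in/out
solver_nonlinear <- function(wh, ops) {
  vel <- solver_velocity_hat(wh, ops)
  u <- ifft_re(vel$uh); v <- ifft_re(vel$vh)
  wx <- ifft_re(1i * ops$KX * wh); wy <- ifft_re(1i * ops$KY * wh)
  nh <- -stats::fft(u * wx + v * wy)
  nh * ops$dealias
}

#' Initialise solver state
#'
#' @param config A [solver_config()].
#' @param noise_amplitude RMS of a small random solenoidal perturbation
#'   seeding symmetry breaking; 0 for a quiescent start.
#' @return A solver state (list with the spectral vorticity `wh`, time `t`,
#'   operators and config), class `solver_state`.
#' @export
solver_init <- function(config, noise_amplitude = 0) {
  ops <- solver_operators(config)
  n <- config$n
  w <- matrix(0, n, n)
  if (noise_amplitude > 0) {
    rs <- local_rng(config$seed)
    w <- matrix(rs$rnorm(n * n), n, n)
    wh <- stats::fft(w) * ops$dealias
    wh[1, 1] <- 0
    # confine the perturbation to large scales (|k| below 6 fundamental modes)
    kf <- 6 * 2 * pi / config$domain_size
    wh[ops$K2 > kf^2] <- 0
    w <- ifft_re(wh)
    w <- w * noise_amplitude / max(stats::sd(w), .Machine$double.xmin)
  }
  wh <- stats::fft(w); wh[1, 1] <- 0
  structure(list(wh = wh, t = 0, config = config, ops = ops),
            class = "solver_state")
}

#' Advance the solver one time step
#'
#' Integrating-factor RK4: the viscous and friction terms decay exactly as
#' `exp(-(nu k^2 + alpha) dt)` while the dealiased nonlinear term and the
#' forcing are advanced with classical RK4. Aborts with a diagnostic if
#' the state becomes non-finite.
#'
#' @param state A solver state from [solver_init()].
#' @param forcing `NULL`, or a function `(t, ops)` returning the spectral
#'   vorticity forcing matrix at time `t`.
#' @return The advanced state.
#' @export
solver_step <- function(state, forcing = NULL) {
  ops <- state$ops; dt <- state$config$dt
  rhs <- if (is.null(forcing)) {
    function(wh, t) solver_nonlinear(wh, ops)
  } else {
    function(wh, t) solver_nonlinear(wh, ops) + forcing(t, ops)
  }
  E1 <- exp(-ops$decay * dt / 2); E2 <- E1 * E1
  wh <- state$wh; t <- state$t
  k1 <- rhs(wh, t)
  k2 <- rhs(E1 * (wh + dt / 2 * k1), t + dt / 2)
  k3 <- rhs(E1 * wh + dt / 2 * k2, t + dt / 2)
  k4 <- rhs(E2 * wh + dt * E1 * k3, t + dt)
  wh_new <- E2 * wh + dt / 6 * (E2 * k1 + 2 * E1 * (k2 + k3) + k4)
  if (any(!is.finite(Re(wh_new))))
    stop(sprintf("solver_step: non-finite state at t = %.4f (dt too large or forcing unstable)", t))
  state$wh <- wh_new
  state$t <- t + dt
  state
}

#' Kinetic energy and enstrophy of a solver state
#'
#' Domain-averaged kinetic energy `E = <|u|^2>/2` and enstrophy
#' `Z = <w^2>/2`, computed spectrally (Parseval).
#'
#' @param state A solver state.
#' @return A list with `energy` and `enstrophy`.
#' @export
solver_energy <- function(state) {
  ops <- state$ops
  n2 <- length(state$wh)
  spec <- Mod(state$wh)^2 / n2^2
  list(energy = sum(spec * ops$K2inv) / 2,
       enstrophy = sum(spec) / 2)
}

#' Extract the velocity field of a solver state
#'
#' Velocities come from streamfunction derivatives, so the field is
#' divergence-free to spectral precision.
#'
#' @param state A solver state.
#' @return A [velocity_field()] (single frame) on the solver grid.
#' @export
solver_velocity <- function(state) {
  cfg <- state$config
  vel <- solver_velocity_hat(state$wh, state$ops)
  g <- grid2d(cfg$n, cfg$n, cfg$domain_size / cfg$n, cfg$domain_size / cfg$n,
              x0 = -cfg$domain_size / 2, y0 = -cfg$domain_size / 2)
  f <- velocity_field(g, state$t, ifft_re(vel$uh), ifft_re(vel$vh))
  f$attrs <- list(source = "solver", nu = cfg$nu, alpha = cfg$alpha)
  f
}

#' Forcing specification for solver experiments
#'
#' Combines a steady Kolmogorov-type shear-band force (streamwise body
#' force `F0 sin(k_f x) y-hat`, single cross-stream wavenumber, zero mean)
#' with an optional schedulable angled-jet force: a compact Gaussian
#' momentum source of width `jet_width` at `jet_origin`, pointing at
#' `theta_s` from the shear's extensional eigenvector, ramped over 0.1 s
#' at each switch-on. The jet's polarity alternates between on-cycles:
#' the stress geometry (an axial quantity) is unchanged while the injected
#' mean momentum cancels over the schedule.
#'
#' @param shear_amplitude Body-force amplitude `F0` (cm/s^2).
#' @param shear_mode Cross-stream mode number of the band (default 1).
#' @param jet_amplitude Jet force amplitude (cm/s^2); 0 disables the jet.
#' @param jet_theta_s Angle of the jet axis from the extensional
#'   eigenvector of the band-centre shear, in `[0, pi/2]`.
#' @param jet_width Gaussian width of the jet force (cm).
#' @param jet_origin Jet location, length-2 (cm); default band centre.
#' @param schedule Data frame from [schedule_on_off()], or `NULL` for a
#'   steady jet.
#' @param ramp Switch-on ramp time (s).
#' @return An object of class `forcing_spec`.
#' @export
forcing_spec <- function(shear_amplitude, shear_mode = 1L,
                         jet_amplitude = 0, jet_theta_s = 0,
                         jet_width = 0.8, jet_origin = c(0, 0),
                         schedule = NULL, ramp = 0.1) {
  structure(list(shear_amplitude = shear_amplitude,
                 shear_mode = as.integer(shear_mode),
                 jet_amplitude = jet_amplitude, jet_theta_s = jet_theta_s,
                 jet_width = jet_width, jet_origin = as.numeric(jet_origin),
                 schedule = schedule, ramp = ramp),
            class = "forcing_spec")
}

# activation level of the schedule at time t (with ramp and polarity)
schedule_activation <- function(schedule, t, ramp) {
  if (is.null(schedule)) return(1)
  on <- t >= schedule$on_time & t < schedule$off_time
  if (!any(on)) return(0)
  k <- which(on)[1]
  level <- min(1, (t - schedule$on_time[k]) / max(ramp, 1e-12))
  polarity <- if (k %% 2L == 0L) -1 else 1
  polarity * level
}

# build the spectral vorticity forcing function for a config + spec
make_forcing <- function(config, fspec) {
  ops <- solver_operators(config)
  n <- config$n; D <- config$domain_size
  xs <- -D / 2 + (0:(n - 1)) * D / n
  kf <- 2 * pi * fspec$shear_mode / D
  # steady band: F_y = F0 sin(k_f x) -> vorticity forcing dFy/dx
  band_w <- fspec$shear_amplitude * kf * matrix(cos(kf * xs), n, n)
  band_wh <- stats::fft(band_w) * ops$dealias
  jet_wh <- NULL
  if (fspec$jet_amplitude > 0) {
    # eigenvector of the band-centre shear (dv/dx > 0 at x = 0) is at pi/4
    a <- pi / 4 + fspec$jet_theta_s
    e <- c(cos(a), sin(a))
    X <- matrix(xs, n, n) - fspec$jet_origin[1]
    Y <- matrix(xs, n, n, byrow = TRUE) - fspec$jet_origin[2]
    env <- fspec$jet_amplitude * exp(-(X^2 + Y^2) / (2 * fspec$jet_width^2))
    fx <- stats::fft(env * e[1]); fy <- stats::fft(env * e[2])
    jet_wh <- (1i * ops$KX * fy - 1i * ops$KY * fx) * ops$dealias
  }
  function(t, ops_unused) {
    out <- band_wh
    if (!is.null(jet_wh)) {
      act <- schedule_activation(fspec$schedule, t, fspec$ramp)
      if (act != 0) out <- out + act * jet_wh
    }
    out
  }
}

#' Run a forced solver case
#'
#' Integrates from a (small-noise) initial state under the given forcing
#' and returns sampled velocity frames. Aborts if the kinetic energy
#' exceeds `energy_bound` (instability guard).
#'
#' @param config A [solver_config()].
#' @param fspec A [forcing_spec()].
#' @param duration Integration time (s).
#' @param sample_every Sampling interval in steps (default: ~0.25 s).
#' @param spinup Time (s) discarded before sampling starts.
#' @param noise_amplitude Initial perturbation rms (1/s).
#' @param energy_bound Abort threshold on `<|u|^2>/2` (cm^2/s^2).
#' @return A [velocity_field()] with the sampled frames; the energy time
#'   series and config are carried in `attrs`.
#' @export
run_case <- function(config, fspec, duration, sample_every = NULL,
                     spinup = 0, noise_amplitude = 1e-3,
                     energy_bound = 1e4) {
  state <- solver_init(config, noise_amplitude)
  forcing <- make_forcing(config, fspec)
  n_steps <- ceiling((duration + spinup) / config$dt)
  if (is.null(sample_every)) sample_every <- max(1L, round(0.25 / config$dt))
  frames_u <- list(); frames_v <- list(); frame_t <- numeric(0)
  energy_t <- numeric(0); energy_e <- numeric(0)
  g <- NULL
  for (s in seq_len(n_steps)) {
    state <- solver_step(state, forcing)
    if (s %% sample_every == 0L) {
      en <- solver_energy(state)
      energy_t <- c(energy_t, state$t); energy_e <- c(energy_e, en$energy)
      if (en$energy > energy_bound)
        stop(sprintf("run_case: energy %.3g exceeds bound at t = %.2f (instability)",
                     en$energy, state$t))
      if (state$t > spinup) {
        f <- solver_velocity(state)
        g <- f$grid
        frames_u[[length(frames_u) + 1L]] <- f$u[, , 1]
        frames_v[[length(frames_v) + 1L]] <- f$v[, , 1]
        frame_t <- c(frame_t, state$t)
      }
    }
  }
  if (!length(frame_t)) stop("run_case: no frames sampled; increase duration")
  nu <- array(unlist(frames_u), dim = c(g$nx, g$ny, length(frame_t)))
  nv <- array(unlist(frames_v), dim = c(g$nx, g$ny, length(frame_t)))
  out <- velocity_field(g, frame_t, nu, nv)
  out$attrs <- list(source = "solver", config = unclass(config),
                    forcing = unclass(fspec)[c("shear_amplitude", "shear_mode",
                                               "jet_amplitude", "jet_theta_s",
                                               "jet_width")],
                    energy = data.frame(t = energy_t, energy = energy_e))
  out
}

#' Paired jet/no-jet geometry experiment
#'
#' The in-silico analogue of the angled-needle experiment: a steady
#' Kolmogorov shear band is run once without and once with a scheduled
#' compact jet at angle `theta_s` to the band-centre extensional
#' eigenvector, from identical initial conditions. The normalised mean
#' velocity gradient `P~ = P_jet / P_pure` is measured over a band-centre
#' window; `P~ > 1` means the shear was intensified (inverse-flux
#' geometry), `P~ < 1` attenuated (forward-flux geometry).
#'
#' The measured `P` averages only the frames recorded while the jet acts
#' (each on period plus a short `tail` of decay) — the in-silico analogue
#' of selecting video sections from the start to the full development of
#' the jet.
#'
#' @param config A [solver_config()].
#' @param base_forcing A [forcing_spec()] describing the shear band (its
#'   jet settings are overridden).
#' @param theta_s Jet angle in `[0, pi/2]`.
#' @param duration Sampled experiment length (s).
#' @param spinup Discarded spin-up time (s).
#' @param jet_amplitude Jet force amplitude (cm/s^2).
#' @param window_half_width Band-centre averaging half width (cm); default
#'   an eighth of the domain.
#' @param mean_interval Mean on/off interval of the jet schedule (s).
#' @param tail Post-off decay time (s) still counted as jet-affected.
#' @param without_jet Optional pre-computed reference run (the no-jet case
#'   is theta-independent, so one reference serves all angles).
#' @return A list with `P_tilde`, `P_jet`, `P_pure`, the two sampled
#'   [velocity_field()]s (`with_jet`, `without_jet`) and the window used.
#' @export
run_geometry_experiment <- function(config, base_forcing, theta_s,
                                    duration = 60, spinup = 6,
                                    jet_amplitude = 4,
                                    window_half_width = NULL,
                                    mean_interval = 2, tail = 0.5,
                                    without_jet = NULL) {
  if (theta_s < 0 || theta_s > pi / 2)
    stop("run_geometry_experiment: theta_s must lie in [0, pi/2]")
  if (is.null(window_half_width)) window_half_width <- config$domain_size / 8
  sched <- schedule_on_off(mean_interval, n_cycles = ceiling(duration),
                           seed = config$seed, t0 = spinup, jitter = "uniform")
  f_jet <- forcing_spec(base_forcing$shear_amplitude, base_forcing$shear_mode,
                        jet_amplitude = jet_amplitude, jet_theta_s = theta_s,
                        jet_width = base_forcing$jet_width,
                        jet_origin = base_forcing$jet_origin,
                        schedule = sched, ramp = base_forcing$ramp)
  with_jet <- run_case(config, f_jet, duration, spinup = spinup)
  if (is.null(without_jet)) {
    f_pure <- forcing_spec(base_forcing$shear_amplitude, base_forcing$shear_mode)
    without_jet <- run_case(config, f_pure, duration, spinup = spinup)
  }
  window <- list(xlim = c(-window_half_width, window_half_width),
                 ylim = c(-config$domain_size / 2, config$domain_size / 2))
  jet_frames <- which(vapply(with_jet$times, function(t)
    any(t >= sched$on_time & t <= sched$off_time + tail), logical(1)))
  if (!length(jet_frames)) jet_frames <- seq_along(with_jet$times)
  P_jet <- mean_gradient(with_jet, window, frames = jet_frames)
  P_pure <- mean_gradient(without_jet, window)
  list(P_tilde = normalized_gradient(P_jet, P_pure),
       P_jet = P_jet, P_pure = P_pure,
       theta_s = theta_s, window = window, jet_frames = jet_frames,
       schedule = sched,
       with_jet = with_jet, without_jet = without_jet)
}
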