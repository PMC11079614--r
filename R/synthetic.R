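#' Uniform background-shear specification
#'
#' A streamwise-uniform shear `v(x)` spanning the cross-stream direction,
#' emulating the laboratory shear band whose velocity rises linearly from
#' `-v_max` to `+v_max` across a width `W`. Specify either the shear rate
#' `gamma = dv/dx` directly or the endpoint speed and width
#' (`gamma = 2 v_max / W`).
#'
#' @param gamma Shear rate (1/s); mutually exclusive with `v_max`/`W`.
#' @param v_max Endpoint speed (cm/s), default 1.2.
#' @param W Shear width (cm), default 7.
#' @param profile `"linear"` or `"tanh"` (saturating outside `W`).
#' @param center Cross-stream coordinate where `v = 0` (cm).
#' @return An object of class `shear_spec`.
#' @export
shear_spec <- function(gamma = NULL, v_max = 1.2, W = 7,
                       profile = c("linear", "tanh"), center = 0) {
  profile <- match.arg(profile)
  if (!(W > 0)) stop("shear_spec: W must be positive")
  if (is.null(gamma)) gamma <- 2 * v_max / W else v_max <- gamma * W / 2
  structure(list(gamma = gamma, v_max = v_max, W = W,
                 profile = profile, center = center),
            class = "shear_spec")
}

#' Orientation of a shear's extensional strain eigenvector
#'
#' For `v(x)` with `dv/dx = gamma`, the rate-of-strain tensor is pure
#' off-diagonal and its extensional eigenvector sits at pi/4 to the x axis
#' when `gamma > 0` (3 pi/4 when `gamma < 0`), uniformly over the band.
#'
#' @param spec A [shear_spec()].
#' @return Angle in radians on `[0, pi)`.
#' @export
shear_eigen_angle <- function(spec) {
  stopifnot(inherits(spec, "shear_spec"))
  if (spec$gamma == 0) stop("shear_eigen_angle: undefined for zero shear")
  if (spec$gamma > 0) pi / 4 else 3 * pi / 4
}

#' Generate a background shear field
#'
#' @param spec A [shear_spec()].
#' @param grid A [grid2d()].
#' @param times Time instants (s); the shear is steady, frames identical.
#' @return A [velocity_field()] with `u = 0` and `v = v(x)`.
#' @export
make_shear <- function(spec, grid, times = 0) {
  stopifnot(inherits(spec, "shear_spec"), inherits(grid, "grid2d"))
  co <- grid_coords(grid)
  xi <- co$x - spec$center
  vx <- switch(spec$profile,
               linear = spec$gamma * xi,
               tanh = spec$v_max * tanh(2 * xi / spec$W))
  nt <- length(times)
  v <- array(rep(vx, times = grid$ny * nt), dim = c(grid$nx, grid$ny, nt))
  u <- array(0, dim = dim(v))
  out <- velocity_field(grid, times, u, v)
  out$attrs <- list(source = "shear", gamma = spec$gamma, profile = spec$profile)
  out
}

#' Localised jet specification
#'
#' A steady planar jet issuing from a nozzle, the proxy for the thrust
#' wake behind a centimetre-scale swimmer (or the dispensing-needle jets
#' of the analog experiment). The default `"gaussian-plume"` envelope has
#' axial speed `U(s) = U0 * min(1, sqrt(s0 / s))` along the axis
#' coordinate `s`, a Gaussian cross-profile whose width grows linearly
#' beyond the development length `s0`, and a cross-profile scale chosen so
#' the kinematic momentum flux across any transect is `U0^2 d` (conserved
#' downstream). A `"self-similar-planar"` sech^2 (Bickley-like) profile is
#' available as a shape-sensitivity alternative.
#'
#' @param origin Nozzle position, length-2 (cm).
#' @param axis_angle Jet axis direction, radians from the +y (streamwise)
#'   axis, positive toward +x. `pi/4` aligns the jet with the extensional
#'   eigenvector of a positive shear.
#' @param d Nozzle width (cm), default 0.096 (the 0.96 mm needle).
#' @param U0 Exit speed (cm/s). Default from `discharge`.
#' @param discharge Volumetric rate (mL/min) used with `d` and `layer`
#'   when `U0` is not given; default 6.
#' @param layer Fluid-layer thickness (cm) converting discharge to exit
#'   speed, default 0.5.
#' @param s0 Development length (cm); default `5 * d`.
#' @param envelope `"gaussian-plume"` or `"self-similar-planar"`.
#' @return An object of class `jet_spec`.
#' @export
jet_spec <- function(origin = c(0, 0), axis_angle = 0, d = 0.096,
                     U0 = NULL, discharge = 6, layer = 0.5, s0 = 5 * d,
                     envelope = c("gaussian-plume", "self-similar-planar")) {
  envelope <- match.arg(envelope)
  if (!(d > 0)) stop("jet_spec: nozzle width d must be positive")
  if (is.null(U0)) U0 <- (discharge / 60) / (d * layer)  # mL/min -> cm^3/s over slot area
  if (!(U0 > 0)) stop("jet_spec: exit speed must be positive")
  structure(list(origin = as.numeric(origin), axis_angle = axis_angle,
                 d = d, U0 = U0, s0 = s0, envelope = envelope),
            class = "jet_spec")
}

jet_axis_direction <- function(axis_angle) c(sin(axis_angle), cos(axis_angle))

#' Generate a localised jet field
#'
#' Evaluates the jet of a [jet_spec()] on the grid at time `t` (the jet is
#' steady; scheduling is applied by the scenario layer). The flow is
#' maximal on the axis at the nozzle, decays along and off axis per the
#' envelope, and is smoothly cut off behind the nozzle. If the jet has not
#' decayed below 1% of `U0` at the domain boundary, the returned field is
#' flagged (`attrs$extent_warning`) and a warning is raised.
#'
#' @param spec A [jet_spec()].
#' @param grid A [grid2d()].
#' @param times Time instants; frames are identical.
#' @param divergence_free If `TRUE`, apply a spectral divergence-cleaning
#'   projection on the grid.
#' @return A [velocity_field()].
#' @export
make_jet <- function(spec, grid, times = 0, divergence_free = FALSE) {
  stopifnot(inherits(spec, "jet_spec"), inherits(grid, "grid2d"))
  co <- grid_coords(grid)
  if (spec$origin[1] < min(co$x) || spec$origin[1] > max(co$x) ||
      spec$origin[2] < min(co$y) || spec$origin[2] > max(co$y))
    stop("make_jet: jet origin lies outside the grid")
  e <- jet_axis_direction(spec$axis_angle)
  X <- matrix(co$x, grid$nx, grid$ny) - spec$origin[1]
  Y <- matrix(co$y, grid$nx, grid$ny, byrow = TRUE) - spec$origin[2]
  s <- X * e[1] + Y * e[2]          # along-axis coordinate
  n <- -X * e[2] + Y * e[1]         # cross-axis coordinate
  sp <- pmax(s, 0)
  if (spec$envelope == "gaussian-plume") {
    b0 <- spec$d / sqrt(pi)         # momentum flux U^2 b sqrt(pi) = U0^2 d
    U <- spec$U0 * pmin(1, sqrt(spec$s0 / pmax(sp, .Machine$double.eps)))
    b <- b0 * pmax(1, sp / spec$s0)
    speed <- U * exp(-n^2 / (2 * b^2))
  } else {
    b0 <- 3 * spec$d / 4            # momentum flux U^2 b * 4/3 = U0^2 d
    U <- spec$U0 * pmin(1, sqrt(spec$s0 / pmax(sp, .Machine$double.eps)))
    b <- b0 * pmax(1, sp / spec$s0)
    speed <- U / cosh(n / b)^2
  }
  # smooth cut-off behind the nozzle exit
  behind <- s < 0
  speed[behind] <- speed[behind] * exp(-(s[behind] / spec$d)^2)
  u1 <- speed * e[1]; v1 <- speed * e[2]
  nt <- length(times)
  out <- velocity_field(grid, times,
                        array(u1, dim = c(grid$nx, grid$ny, nt)),
                        array(v1, dim = c(grid$nx, grid$ny, nt)))
  if (divergence_free) out <- divergence_clean(out)
  bmax <- max(abs(speed[1, ]), abs(speed[grid$nx, ]),
              abs(speed[, 1]), abs(speed[, grid$ny]))
  out$attrs <- list(source = "jet", U0 = spec$U0, d = spec$d,
                    axis_angle = spec$axis_angle,
                    extent_warning = bmax > 0.01 * spec$U0)
  if (out$attrs$extent_warning)
    warning("make_jet: jet has not decayed below 1% of U0 at the domain boundary")
  out
}

#' Project a field onto its divergence-free part
#'
#' Spectral Helmholtz projection (periodic-extension based): removes the
#' irrotational component so the flux formulas' incompressibility
#' assumption holds exactly on the grid.
#'
#' @param field A [velocity_field()].
#' @return A [velocity_field()] with zero discrete (spectral) divergence.
#' @export
divergence_clean <- function(field) {
  g <- field$grid
  kx <- fft_wavenumbers(g$nx, g$dx)
  ky <- fft_wavenumbers(g$ny, g$dy)
  KX <- matrix(kx, g$nx, g$ny)
  KY <- matrix(ky, g$nx, g$ny, byrow = TRUE)
  K2 <- KX^2 + KY^2; K2[1, 1] <- 1
  # the unpaired Nyquist modes of an even-length grid cannot carry a real
  # solenoidal representation; annihilate them along with the projection
  nyq <- matrix(1, g$nx, g$ny)
  if (g$nx %% 2L == 0L) nyq[g$nx / 2 + 1, ] <- 0
  if (g$ny %% 2L == 0L) nyq[, g$ny / 2 + 1] <- 0
  u <- field$u; v <- field$v
  for (k in seq_len(dim(u)[3])) {
    uh <- stats::fft(u[, , k]) * nyq; vh <- stats::fft(v[, , k]) * nyq
    div <- (KX * uh + KY * vh) / K2
    uh <- uh - KX * div; vh <- vh - KY * div
    u[, , k] <- Re(stats::fft(uh, inverse = TRUE)) / (g$nx * g$ny)
    v[, , k] <- Re(stats::fft(vh, inverse = TRUE)) / (g$nx * g$ny)
  }
  out <- velocity_field(g, field$times, u, v, field$mask)
  out$attrs <- c(field$attrs, list(divergence_free = TRUE))
  out
}

#' Swimmer event: a moving agitation source in the shear
#'
#' A centimetre-scale swimmer propelling itself leaves a jet pointing
#' opposite to its swimming direction. `theta_s` is the folded angle
#' between the swimming direction and the extensional eigenvector of the
#' background shear's rate of strain; it is the geometric control
#' parameter of the analysis. Give either `swim_direction` or `theta_s`
#' (the direction is then placed at `theta_s` from the eigenvector of
#' `shear`).
#'
#' @param position Swimmer position: length-2 (static) or `function(t)`
#'   returning length-2 (cm).
#' @param swim_direction Length-2 direction of travel (normalised
#'   internally).
#' @param theta_s Target angle in `[0, pi/2]`; requires `shear`.
#' @param shear A [shear_spec()] fixing the eigenframe when `theta_s` is
#'   given.
#' @return An object of class `swimmer_event`.
#' @export
swimmer_event <- function(position = c(0, 0), swim_direction = NULL,
                          theta_s = NULL, shear = NULL) {
  if (is.null(swim_direction)) {
    if (is.null(theta_s) || is.null(shear))
      stop("swimmer_event: give swim_direction, or theta_s together with shear")
    if (theta_s < 0 || theta_s > pi / 2)
      stop("swimmer_event: theta_s must lie in [0, pi/2]")
    a <- shear_eigen_angle(shear) + theta_s
    swim_direction <- c(cos(a), sin(a))
  }
  nrm <- sqrt(sum(swim_direction^2))
  if (!(nrm > 0)) stop("swimmer_event: zero swim direction")
  swim_direction <- swim_direction / nrm
  structure(list(position = position, swim_direction = swim_direction,
                 theta_s = theta_s),
            class = "swimmer_event")
}

#' Velocity field of a swimmer in a background shear
#'
#' Superposes the background shear with a jet anchored at the swimmer's
#' position and pointing opposite to its swimming direction. The realised
#' `theta_s` (folded angle between swimming direction and the shear's
#' extensional eigenvector) is recorded in `attrs$theta_s`; if the event
#' carries a target `theta_s` it must agree to 1e-9.
#'
#' @param event A [swimmer_event()].
#' @param shear A [shear_spec()].
#' @param grid A [grid2d()].
#' @param times Time instants (s); a moving swimmer is evaluated per frame.
#' @param jet A [jet_spec()] giving the wake-jet shape; origin and axis are
#'   overridden per frame. Default: a body-scale wake (`d = 0.5` cm wide for
#'   a centimetre-scale swimmer, `U0 = 3` cm/s).
#' @return A [velocity_field()].
#' @export
swimmer_field <- function(event, shear, grid, times = 0, jet = NULL) {
  stopifnot(inherits(event, "swimmer_event"), inherits(shear, "shear_spec"))
  if (is.null(jet)) jet <- jet_spec(d = 0.5, U0 = 3, s0 = 1.5)
  theta_real <- fold_axial_angle(
    atan2(event$swim_direction[2], event$swim_direction[1]) - shear_eigen_angle(shear))
  if (!is.null(event$theta_s) && abs(theta_real - event$theta_s) > 1e-9)
    stop(sprintf("swimmer_field: realised theta_s (%.12f) differs from event theta_s (%.12f)",
                 theta_real, event$theta_s))
  # jet axis: opposite the swimming direction; axis_angle measured from +y
  jet_dir <- -event$swim_direction
  axis_angle <- atan2(jet_dir[1], jet_dir[2])
  base <- make_shear(shear, grid, times)
  nt <- length(times)
  for (k in seq_len(nt)) {
    pos <- if (is.function(event$position)) event$position(times[k]) else event$position
    jk <- jet_spec(origin = pos, axis_angle = axis_angle, d = jet$d,
                   U0 = jet$U0, s0 = jet$s0, envelope = jet$envelope)
    jf <- suppressWarnings(make_jet(jk, grid, times = times[k]))
    base$u[, , k] <- base$u[, , k] + jf$u[, , 1]
    base$v[, , k] <- base$v[, , k] + jf$v[, , 1]
  }
  base$attrs <- list(source = "swimmer_in_shear", theta_s = theta_real,
                     gamma = shear$gamma,
                     swim_direction = event$swim_direction)
  base
}

#' Intermittent on/off schedule
#'
#' Emulates a jet switched on and off intermittently at a stated mean
#' interval (the laboratory protocol used 14 s). Two jitter models:
#' `"exponential"` (memoryless switching, the default for swimmer-like
#' intermittency) and `"uniform"` (durations uniform in 0.6-1.4 times the
#' mean, emulating a roughly regular pump cycle).
#'
#' @param mean_interval Mean interval length (s), default 14.
#' @param n_cycles Number of on periods.
#' @param seed Integer seed; the schedule is reproducible.
#' @param t0 Schedule start time (s).
#' @param jitter `"exponential"` or `"uniform"`.
#' @return A data frame with columns `on_time`, `off_time` (one row per on
#'   period).
#' @export
schedule_on_off <- function(mean_interval = 14, n_cycles, seed = 1L, t0 = 0,
                            jitter = c("exponential", "uniform")) {
  jitter <- match.arg(jitter)
  if (!(mean_interval > 0)) stop("schedule_on_off: mean_interval must be positive")
  if (n_cycles == 0)
    return(data.frame(on_time = numeric(0), off_time = numeric(0)))
  rs <- local_rng(seed)
  durs <- if (jitter == "exponential")
    rs$rexp(2L * n_cycles, rate = 1 / mean_interval)
  else mean_interval * rs$runif(2L * n_cycles, 0.6, 1.4)
  edges <- t0 + cumsum(c(0, durs))
  data.frame(on_time = edges[seq(1, 2 * n_cycles, by = 2)],
             off_time = edges[seq(2, 2 * n_cycles, by = 2)])
}

# private RNG stream: draws do not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rexp = function(...) draw(stats::rexp, ...),
       runif = function(...) draw(stats::runif, ...),
       rnorm = function(...) draw(stats::rnorm, ...))
}

#' Stokes number of a tracer particle
#'
#' `St = tau_p / tau_f` with particle response time
#' `tau_p = rho_p d^2 / (18 rho_f nu)`. Small values (the laboratory
#' tracers are of order 1e-3) mean the particles follow the flow
#' faithfully.
#'
#' @param d_particle Particle diameter (cm).
#' @param rho_particle,rho_fluid Densities (g/cm^3).
#' @param nu_fluid Kinematic viscosity (cm^2/s).
#' @param flow_timescale Characteristic flow time (s), e.g. `1 / gamma`.
#' @return Dimensionless Stokes number.
#' @export
stokes_number <- function(d_particle, rho_particle, rho_fluid, nu_fluid,
                          flow_timescale) {
  vals <- c(d_particle, rho_particle, rho_fluid, nu_fluid, flow_timescale)
  if (any(!(vals > 0))) stop("stokes_number: all inputs must be positive")
  tau_p <- rho_particle * d_particle^2 / (18 * rho_fluid * nu_fluid)
  tau_p / flow_timescale
}
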