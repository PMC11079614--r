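check_tensor_pair <- function(tau, S, strict_meta = TRUE) {
  stopifnot(inherits(tau, "tensor_field"), inherits(S, "tensor_field"))
  if (!same_grid(tau$grid, S$grid)) stop("tensor fields are on different grids")
  if (length(tau$times) != length(S$times))
    stop("tensor fields have different numbers of frames")
  if (strict_meta) {
    for (key in c("kernel", "L")) {
      a <- tau$attrs[[key]]; b <- S$attrs[[key]]
      if (!is.null(a) && !is.null(b) && !identical(a, b))
        stop(sprintf("tensor metadata mismatch: %s is %s vs %s",
                     key, format(a), format(b)))
    }
  }
  invisible(TRUE)
}

#' Pointwise spectral energy flux Q(L)
#'
#' The energy transfer through scale `L` is the contraction of the
#' turbulent stress against the filtered rate of strain,
#' `Q(L) = -tau_ij(L) S_ij(L)`
#' `= -(txx Sxx + 2 txy Sxy + tyy Syy)` per node. Negative `Q` is inverse
#' flux (energy moving to larger scales); positive `Q` is forward flux
#' (toward smaller scales).
#'
#' @param tau A stress [tensor_field()] (cm^2/s^2), e.g. from
#'   [turbulent_stress()].
#' @param S The rate-of-strain [tensor_field()] (1/s) of the velocity field
#'   filtered at the same `L` with the same kernel.
#' @return A [scalar_field()] of flux density in cm^2/s^3.
#' @export
flux_pointwise <- function(tau, S) {
  check_tensor_pair(tau, S)
  q <- -(tau$txx * S$txx + 2 * tau$txy * S$txy + tau$tyy * S$tyy)
  scalar_field(tau$grid, tau$times, q, units = "cm^2/s^3",
               attrs = c(tau$attrs[c("kernel", "L", "padding", "interior_margin")],
                         list(quantity = "Q")))
}

#' Pointwise flux from the subgrid Reynolds stress, Qs(L)
#'
#' `Qs = -tauS_ij(L) S_ij(L)`. Identical contraction to
#' [flux_pointwise()], applied to the subgrid-scale Reynolds stress — the
#' component that dominates the net flux while being free of the
#' edge-padding contamination that afflicts the Leonard and cross terms in
#' a finite interrogation window.
#'
#' @param tauS The subgrid Reynolds stress from [sgs_reynolds_stress()].
#' @inheritParams flux_pointwise
#' @return A [scalar_field()] (cm^2/s^3) with `attrs$quantity = "Qs"`.
#' @export
sgs_flux_pointwise <- function(tauS, S) {
  out <- flux_pointwise(tauS, S)
  out$attrs$quantity <- "Qs"
  out
}

#' Energy flux from tensor geometry
#'
#' In 2-D the contraction of two deviatoric symmetric tensors reduces to
#' `Q = -2 lambda_tau lambda_S cos(2 theta)`, where the lambdas are the
#' largest deviatoric eigenvalues and `theta` is the angle between the
#' extensional eigenvectors. `cos(2 theta)` acts as the efficiency of the
#' cross-scale transfer: flux vanishes at `theta = pi/4` (perfect
#' misalignment), is maximally inverse at `theta = 0` and maximally
#' forward at `theta = pi/2`.
#'
#' @param lambda_tau,lambda_S Largest deviatoric eigenvalues (>= 0);
#'   scalars or arrays.
#' @param theta Alignment angle(s) in radians, folded to `[0, pi/2]`.
#' @return Flux density of the same shape as the inputs.
#' @export
flux_from_geometry <- function(lambda_tau, lambda_S, theta) {
  if (any(lambda_tau < 0, na.rm = TRUE) || any(lambda_S < 0, na.rm = TRUE))
    stop("flux_from_geometry: eigenvalues must be non-negative")
  if (any(theta < -1e-12 | theta > pi / 2 + 1e-12, na.rm = TRUE))
    stop("flux_from_geometry: theta must lie in [0, pi/2]")
  # cospi keeps the pi/4 zero crossing exact in floating point
  -2 * lambda_tau * lambda_S * cospi(2 * theta / pi)
}

# fold a difference of axial orientations into [0, pi/2]
fold_axial_angle <- function(delta) {
  d <- abs(delta) %% pi
  ifelse(d > pi / 2, pi - d, d)
}

#' Eigenframe alignment between stress and rate of strain
#'
#' Computes, per node, the largest deviatoric eigenvalues of the stress and
#' the strain and the folded angle `theta` in `[0, pi/2]` between their
#' extensional eigenvectors. `theta` is defined only where both eigenframes
#' are non-degenerate (NA elsewhere).
#'
#' @inheritParams flux_pointwise
#' @return An object of class `geometry_field` with array fields
#'   `lambda_tau`, `lambda_S`, `theta`.
#' @export
alignment_angle <- function(tau, S) {
  check_tensor_pair(tau, S)
  et <- eigenframe(tau); es <- eigenframe(S)
  theta <- fold_axial_angle(et$angle - es$angle)
  structure(list(grid = tau$grid, times = tau$times,
                 lambda_tau = et$lambda, lambda_S = es$lambda, theta = theta,
                 attrs = tau$attrs[c("kernel", "L", "padding", "interior_margin")]),
            class = "geometry_field")
}

#' @export
print.geometry_field <- function(x, ...) {
  cat(sprintf("<geometry_field> %d frame(s); median theta %.3f rad (pi/4 = %.3f); %.1f%% degenerate\n",
              length(x$times), stats::median(x$theta, na.rm = TRUE), pi / 4,
              100 * mean(is.na(x$theta))))
  invisible(x)
}

frame_region_mean <- function(values, grid, margin, region = NULL) {
  if (is.null(region)) {
    idx <- interior_indices(grid, margin)
  } else {
    co <- grid_coords(grid)
    idx <- interior_indices(grid, margin)
    idx$ix <- idx$ix[co$x[idx$ix] >= min(region$xlim) & co$x[idx$ix] <= max(region$xlim)]
    idx$iy <- idx$iy[co$y[idx$iy] >= min(region$ylim) & co$y[idx$iy] <= max(region$ylim)]
    if (!length(idx$ix) || !length(idx$iy))
      stop("averaging region is empty after excluding the filter margin")
  }
  nt <- dim(values)[3]
  vapply(seq_len(nt), function(k)
    mean(values[idx$ix, idx$iy, k], na.rm = TRUE), numeric(1))
}

#' Net spectral energy flux versus cutoff scale
#'
#' For each cutoff `L`, filters the field, forms the subgrid Reynolds
#' stress (default) or full stress, contracts it with the filtered rate of
#' strain and averages the pointwise flux over the analysis region
#' (interior margin of `L/2` excluded per side), space first and then
#' time. The per-frame spread is reported as the dispersion.
#'
#' @param field A [velocity_field()].
#' @param L_list Increasing cutoff lengths (cm).
#' @param spec_template A [filter_spec()] supplying kernel and padding.
#' @param region Optional list with `xlim`, `ylim` (cm) restricting the
#'   average, e.g. a near-jet window.
#' @param stress `"sgs"` (Qs, default) or `"full"` (Q).
#' @param derivative Passed to [strain_rate()].
#' @return A data frame of class `flux_curve` with columns `L`, `mean`,
#'   `sd`, `se`, `n_frames`; kernel metadata in attributes.
#' @export
net_flux_curve <- function(field, L_list, spec_template = filter_spec(1),
                           region = NULL, stress = c("sgs", "full"),
                           derivative = c("finite_difference", "spectral")) {
  stress <- match.arg(stress)
  derivative <- match.arg(derivative)
  if (length(L_list) == 0) stop("net_flux_curve: L_list is empty")
  if (any(diff(L_list) <= 0)) stop("net_flux_curve: L_list must be increasing")
  rows <- lapply(L_list, function(L) {
    spec <- filter_spec(L, spec_template$kernel, spec_template$padding,
                        interior_margin = L / 2)
    tau <- if (stress == "sgs") sgs_reynolds_stress(field, spec)
           else turbulent_stress(field, spec)
    S <- strain_rate(lowpass(field, spec), method = derivative)
    q <- if (stress == "sgs") sgs_flux_pointwise(tau, S) else flux_pointwise(tau, S)
    per_frame <- frame_region_mean(q$values, field$grid, spec$interior_margin, region)
    data.frame(L = L, mean = mean(per_frame),
               sd = stats::sd(per_frame),
               se = stats::sd(per_frame) / sqrt(length(per_frame)),
               n_frames = length(per_frame))
  })
  out <- do.call(rbind, rows)
  attr(out, "kernel") <- spec_template$kernel
  attr(out, "padding") <- spec_template$padding
  attr(out, "stress") <- stress
  attr(out, "region") <- region
  class(out) <- c("flux_curve", "data.frame")
  out
}

#' @export
print.flux_curve <- function(x, ...) {
  cat(sprintf("<flux_curve> %s stress, %s kernel; Qbar in cm^2/s^3\n",
              attr(x, "stress"), attr(x, "kernel")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.flux_curve <- function(x, ...) {
  graphics::plot(x$L, x$mean, type = "b", pch = 16,
                 xlab = "L (cm)", ylab = expression(bar(Q)[s] ~ (cm^2/s^3)), ...)
  graphics::arrows(x$L, x$mean - x$se, x$L, x$mean + x$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Classify a swimming direction against the shear eigenframe
#'
#' `theta_s` is the folded angle between a swimmer's direction of travel
#' and the extensional eigenvector of the background shear's rate-of-strain
#' tensor. `theta_s < pi/4` predicts inverse flux (`"aligned"`),
#' `theta_s > pi/4` forward flux (`"anti_aligned"`), and a band of width
#' `2 * tolerance_band` around `pi/4` is `"neutral"`.
#'
#' @param swim_direction Length-2 numeric vector (need not be normalised).
#' @param shear_eigen_angle Orientation of the extensional eigenvector,
#'   radians from +x (pi/4 for a uniform shear `v(x)` with positive
#'   gradient).
#' @param tolerance_band Half-width of the neutral band (radians); default
#'   5 degrees.
#' @return A list with `theta_s` (radians in `[0, pi/2]`) and `category`.
#' @export
classify_theta_s <- function(swim_direction, shear_eigen_angle,
                             tolerance_band = pi / 36) {
  nrm <- sqrt(sum(swim_direction^2))
  if (!(nrm > 0)) stop("classify_theta_s: zero-length direction")
  dir_angle <- atan2(swim_direction[2], swim_direction[1])
  theta_s <- fold_axial_angle(dir_angle - shear_eigen_angle)
  category <- if (abs(theta_s - pi / 4) <= tolerance_band) "neutral"
              else if (theta_s < pi / 4) "aligned" else "anti_aligned"
  list(theta_s = theta_s, category = category)
}

#' Effective (possibly negative) eddy viscosity
#'
#' Recasts the pointwise flux as an effective viscosity
#' `nu_e = Q / (2 S_ij S_ij)`: positive where the sub-filter motions drain
#' the resolved flow like an ordinary viscosity, negative where inverse
#' flux feeds the resolved scales. Nodes with negligible strain
#' (`S_ij S_ij < 1e-14` of its rms) are masked.
#'
#' @param Q_field A [scalar_field()] of flux density.
#' @param S_field The matching rate-of-strain [tensor_field()].
#' @return A [scalar_field()] of viscosity (cm^2/s).
#' @export
effective_viscosity <- function(Q_field, S_field) {
  stopifnot(inherits(Q_field, "scalar_field"), inherits(S_field, "tensor_field"))
  if (!same_grid(Q_field$grid, S_field$grid)) stop("grid mismatch")
  ss <- S_field$txx^2 + 2 * S_field$txy^2 + S_field$tyy^2
  floor_ss <- 1e-14 * mean(ss, na.rm = TRUE)
  nu_e <- Q_field$values / (2 * ss)
  nu_e[ss < floor_ss] <- NA_real_
  nu_e[Q_field$values == 0] <- 0
  scalar_field(Q_field$grid, Q_field$times, nu_e, units = "cm^2/s",
               attrs = c(Q_field$attrs, list(quantity = "nu_effective")))
}
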