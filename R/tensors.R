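# filtered outer products of two component sets; returns list(txx, txy, tyy)
filtered_outer <- function(au, av, bu, bv, grid, spec, mask = NULL) {
  f <- function(a, b) filter_cube(a * b, grid$dx, grid$dy, spec, mask)
  list(txx = f(au, bu),
       txy = (f(au, bv) + f(av, bu)) / 2,
       tyy = f(av, bv))
}

stress_attrs <- function(spec) {
  list(kernel = spec$kernel, L = spec$L, padding = spec$padding,
       interior_margin = spec$interior_margin)
}

#' Turbulent stress tensor at cutoff scale L
#'
#' Computes `tau_ij(L) = (u_i u_j)^(L) - u_i^(L) u_j^(L)`, the stress
#' exerted by sub-filter motions on the resolved flow. Symmetric by
#' construction; units cm^2/s^2.
#'
#' @param field A [velocity_field()].
#' @param spec A [filter_spec()].
#' @return A [tensor_field()] carrying kernel/L metadata.
#' @export
turbulent_stress <- function(field, spec) {
  stopifnot(inherits(field, "velocity_field"), inherits(spec, "filter_spec"))
  g <- field$grid
  lp <- lowpass(field, spec)
  pr <- filtered_outer(field$u, field$v, field$u, field$v, g, spec, field$mask)
  tensor_field(g, field$times,
               pr$txx - lp$u * lp$u,
               pr$txy - (lp$u * lp$v + lp$v * lp$u) / 2,
               pr$tyy - lp$v * lp$v,
               units = "cm^2/s^2", attrs = stress_attrs(spec))
}

#' Subgrid-scale Reynolds stress
#'
#' Computes `tauS_ij(L) = ((u_i - u_i^(L))(u_j - u_j^(L)))^(L)`: the
#' filtered outer product of the residual velocities. Under an
#' everywhere-positive kernel (gaussian, top-hat) this tensor is
#' positive-semidefinite at every interior node, and it carries the
#' dominant share of the net cross-scale energy flux.
#'
#' @inheritParams turbulent_stress
#' @return A [tensor_field()].
#' @export
sgs_reynolds_stress <- function(field, spec) {
  stopifnot(inherits(field, "velocity_field"), inherits(spec, "filter_spec"))
  r <- residual(field, spec)
  pr <- filtered_outer(r$u, r$v, r$u, r$v, field$grid, spec, field$mask)
  tensor_field(field$grid, field$times, pr$txx, pr$txy, pr$tyy,
               units = "cm^2/s^2",
               attrs = c(stress_attrs(spec), list(component = "sgs_reynolds")))
}

#' Leonard and cross stresses
#'
#' The classical triad decomposition of the turbulent stress:
#' Leonard `L_ij = (u_i^(L) u_j^(L))^(L) - u_i^(L) u_j^(L)` (resolved-resolved),
#' cross `C_ij = (u_i^(L) r_j)^(L) + (r_i u_j^(L))^(L)` with residual
#' `r = u - u^(L)` (resolved-residual). Together with the subgrid
#' Reynolds stress they satisfy `tau = L + C + tauS` exactly, by linearity
#' of the filter.
#'
#' @inheritParams turbulent_stress
#' @return A list with [tensor_field()] elements `leonard` and `cross`.
#' @export
leonard_cross_stresses <- function(field, spec) {
  stopifnot(inherits(field, "velocity_field"), inherits(spec, "filter_spec"))
  g <- field$grid
  lp <- lowpass(field, spec)
  r <- residual(field, spec)
  pl <- filtered_outer(lp$u, lp$v, lp$u, lp$v, g, spec, field$mask)
  leonard <- tensor_field(g, field$times,
                          pl$txx - lp$u * lp$u,
                          pl$txy - lp$u * lp$v,
                          pl$tyy - lp$v * lp$v,
                          units = "cm^2/s^2",
                          attrs = c(stress_attrs(spec), list(component = "leonard")))
  f <- function(a, b) filter_cube(a * b, g$dx, g$dy, spec, field$mask)
  cxx <- f(lp$u, r$u) + f(r$u, lp$u)
  cxy <- (f(lp$u, r$v) + f(r$u, lp$v) + f(lp$v, r$u) + f(r$v, lp$u)) / 2
  cyy <- f(lp$v, r$v) + f(r$v, lp$v)
  cross <- tensor_field(g, field$times, cxx, cxy, cyy,
                        units = "cm^2/s^2",
                        attrs = c(stress_attrs(spec), list(component = "cross")))
  list(leonard = leonard, cross = cross)
}

#' Germano decomposition of the turbulent stress
#'
#' Galilean-invariant reformulation of the Leonard/cross/Reynolds split in
#' terms of generalised central moments
#' `m(a, b) = (a b)^(L) - a^(L) b^(L)`:
#' `L^G_ij = m(u_i^(L), u_j^(L))`, `C^G_ij = m(u_i^(L), r_j) + m(r_i, u_j^(L))`,
#' `R^G_ij = m(r_i, r_j)`. Each component is unchanged by adding a uniform
#' velocity offset, and the three again sum exactly to `tau`.
#'
#' @inheritParams turbulent_stress
#' @return A list with [tensor_field()] elements `leonard`, `cross`,
#'   `reynolds`.
#' @export
germano_decomposition <- function(field, spec) {
  stopifnot(inherits(field, "velocity_field"), inherits(spec, "filter_spec"))
  g <- field$grid
  lp <- lowpass(field, spec)
  r <- residual(field, spec)
  flt <- function(a) filter_cube(a, g$dx, g$dy, spec, field$mask)
  cm <- function(a, b) flt(a * b) - flt(a) * flt(b)
  mk <- function(xx, xy, yy, comp)
    tensor_field(g, field$times, xx, xy, yy, units = "cm^2/s^2",
                 attrs = c(stress_attrs(spec), list(component = comp)))
  leonard <- mk(cm(lp$u, lp$u),
                (cm(lp$u, lp$v) + cm(lp$v, lp$u)) / 2,
                cm(lp$v, lp$v), "germano_leonard")
  cross <- mk(cm(lp$u, r$u) + cm(r$u, lp$u),
              (cm(lp$u, r$v) + cm(r$u, lp$v) + cm(lp$v, r$u) + cm(r$v, lp$u)) / 2,
              cm(lp$v, r$v) + cm(r$v, lp$v), "germano_cross")
  reynolds <- mk(cm(r$u, r$u),
                 (cm(r$u, r$v) + cm(r$v, r$u)) / 2,
                 cm(r$v, r$v), "germano_reynolds")
  list(leonard = leonard, cross = cross, reynolds = reynolds)
}

# d/dx and d/dy of one frame: 2nd-order centred interior, one-sided edges
ddx_matrix <- function(m, d) {
  n <- nrow(m)
  out <- m
  out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * d)
  out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * d)
  out[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / (2 * d)
  out
}
ddy_matrix <- function(m, d) t(ddx_matrix(t(m), d))

# spectral derivative (periodic fields only)
ddx_spectral <- function(m, d) {
  kx <- fft_wavenumbers(nrow(m), d)
  Re(stats::fft(stats::fft(m) * (1i * kx), inverse = TRUE)) / length(m)
}
ddy_spectral <- function(m, d) t(ddx_spectral(t(m), d))

#' Rate-of-strain tensor of a (filtered) velocity field
#'
#' `S_ij = (1/2)(d u_i / d x_j + d u_j / d x_i)`, the symmetric part of the
#' velocity gradient. Derivatives use 2nd-order centred finite differences
#' in the interior and one-sided stencils at edges (exact for linear
#' fields), so the same code path serves non-periodic measurement-like
#' fields and solver output; spectral differentiation is available for
#' periodic fields.
#'
#' @param field A [velocity_field()], normally the output of [lowpass()].
#' @param method `"finite_difference"` (default) or `"spectral"`
#'   (doubly periodic fields only).
#' @return A [tensor_field()] in 1/s, inheriting the field's kernel/L
#'   metadata.
#' @export
strain_rate <- function(field, method = c("finite_difference", "spectral")) {
  stopifnot(inherits(field, "velocity_field"))
  method <- match.arg(method)
  g <- field$grid
  nt <- length(field$times)
  sxx <- field$u; sxy <- field$u; syy <- field$u
  dx1 <- if (method == "spectral") ddx_spectral else ddx_matrix
  dy1 <- if (method == "spectral") ddy_spectral else ddy_matrix
  for (k in seq_len(nt)) {
    dudx <- dx1(field$u[, , k], g$dx); dudy <- dy1(field$u[, , k], g$dy)
    dvdx <- dx1(field$v[, , k], g$dx); dvdy <- dy1(field$v[, , k], g$dy)
    sxx[, , k] <- dudx
    sxy[, , k] <- (dudy + dvdx) / 2
    syy[, , k] <- dvdy
  }
  tensor_field(g, field$times, sxx, sxy, syy, units = "1/s",
               attrs = field$attrs)
}

#' Deviatoric part of a tensor field
#'
#' Removes the isotropic part: `T - (tr T / 2) I`. In 2-D the deviatoric
#' eigenvalues are an equal-and-opposite pair, so the eigenframe is fully
#' described by the largest eigenvalue and the extensional-axis angle.
#'
#' @param T A [tensor_field()].
#' @return A traceless [tensor_field()].
#' @export
deviatoric <- function(T) {
  stopifnot(inherits(T, "tensor_field"))
  half_tr <- (T$txx + T$tyy) / 2
  tensor_field(T$grid, T$times, T$txx - half_tr, T$txy, T$tyy - half_tr,
               units = T$units, attrs = c(T$attrs, list(deviatoric = TRUE)))
}

#' Eigenframe of a symmetric tensor field
#'
#' For the deviatoric part of each nodal tensor, returns the largest
#' eigenvalue `lambda` (>= 0) and the orientation `angle` of the
#' extensional eigenvector, measured from the +x axis on `[0, pi)` (an
#' axial quantity). Nodes whose deviatoric magnitude falls below
#' `degeneracy_tol` times the per-frame rms tensor norm are degenerate —
#' the orientation is undefined there and reported as `NA`.
#'
#' @param T A [tensor_field()].
#' @param degeneracy_tol Relative threshold for flagging isotropic nodes.
#' @return An object of class `eigenframe_field` with array fields
#'   `lambda` and `angle` plus the source metadata.
#' @export
eigenframe <- function(T, degeneracy_tol = 1e-12) {
  stopifnot(inherits(T, "tensor_field"))
  dev <- deviatoric(T)
  a <- dev$txx; b <- dev$txy
  lambda <- sqrt(a^2 + b^2)
  angle <- atan2(b, a) / 2
  angle <- angle %% pi
  nt <- length(T$times)
  for (k in seq_len(nt)) {
    nrm <- sqrt(mean(T$txx[, , k]^2 + 2 * T$txy[, , k]^2 + T$tyy[, , k]^2,
                     na.rm = TRUE))
    deg <- lambda[, , k] < degeneracy_tol * max(nrm, .Machine$double.xmin)
    ang <- angle[, , k]; ang[deg] <- NA_real_
    angle[, , k] <- ang
  }
  structure(list(grid = T$grid, times = T$times,
                 lambda = lambda, angle = angle,
                 units = T$units, attrs = T$attrs),
            class = "eigenframe_field")
}

#' @export
print.eigenframe_field <- function(x, ...) {
  cat(sprintf("<eigenframe_field> %d frame(s) on %d x %d grid; mean lambda %.4g%s; %.1f%% degenerate\n",
              length(x$times), x$grid$nx, x$grid$ny,
              mean(x$lambda, na.rm = TRUE),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              100 * mean(is.na(x$angle))))
  invisible(x)
}
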