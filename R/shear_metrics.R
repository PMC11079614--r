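window_indices <- function(grid, window = NULL) {
  co <- grid_coords(grid)
  ix <- seq_len(grid$nx); iy <- seq_len(grid$ny)
  if (!is.null(window)) {
    if (!is.null(window$xlim))
      ix <- ix[co$x[ix] >= min(window$xlim) & co$x[ix] <= max(window$xlim)]
    if (!is.null(window$ylim))
      iy <- iy[co$y[iy] >= min(window$ylim) & co$y[iy] <= max(window$ylim)]
  }
  if (!length(ix) || !length(iy)) stop("analysis window is empty")
  list(ix = ix, iy = iy, x = co$x[ix], y = co$y[iy])
}

#' Streamwise-averaged velocity profile
#'
#' The mean `v` component versus `x`: averaged over the streamwise (`y`)
#' direction and over time within the window, then normalised to zero at
#' `x = 0` (linear interpolation when `x = 0` falls between nodes).
#'
#' @param field A [velocity_field()].
#' @param window Optional list with `xlim` and/or `ylim` (cm).
#' @param frames Optional frame indices to include (e.g. jet-developed
#'   frames only); default all.
#' @return A data frame with columns `x`, `v`.
#' @export
v_profile <- function(field, window = NULL, frames = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  idx <- window_indices(field$grid, window)
  if (is.null(frames)) frames <- seq_along(field$times)
  vals <- field$v[idx$ix, idx$iy, frames, drop = FALSE]
  if (!is.null(field$mask)) {
    m <- field$mask[idx$ix, idx$iy, frames, drop = FALSE]
    vals[!m] <- NA_real_
  }
  prof <- apply(vals, 1, mean, na.rm = TRUE)
  x <- idx$x
  v0 <- if (min(x) <= 0 && max(x) >= 0) stats::approx(x, prof, xout = 0)$y
        else prof[which.min(abs(x))]
  data.frame(x = x, v = prof - v0)
}

#' Mean velocity gradient P
#'
#' `P = <dv/dx>`: the spatiotemporal mean of the centred-difference
#' cross-stream gradient of the streamwise velocity over the window — the
#' standard scalar measure of shear strength. For an exactly linear profile it
#' equals the endpoint secant slope. A least-squares alternative (slope of
#' the streamwise-averaged profile) is available since the estimator is
#' not uniquely dictated by the definition.
#'
#' @param field A [velocity_field()].
#' @param window Optional list with `xlim`/`ylim`; must span at least 8
#'   x-nodes.
#' @param frames Optional frame indices to include.
#' @param estimator `"centered_difference"` (default) or
#'   `"least_squares"`.
#' @return The mean gradient in 1/s.
#' @export
mean_gradient <- function(field, window = NULL, frames = NULL,
                          estimator = c("centered_difference", "least_squares")) {
  stopifnot(inherits(field, "velocity_field"))
  estimator <- match.arg(estimator)
  idx <- window_indices(field$grid, window)
  if (length(idx$ix) < 8L) stop("mean_gradient: window must span at least 8 x-nodes")
  if (is.null(frames)) frames <- seq_along(field$times)
  if (estimator == "least_squares") {
    prof <- v_profile(field, window, frames)
    return(unname(stats::coef(stats::lm(v ~ x, data = prof))[2]))
  }
  nxw <- length(idx$ix)
  acc <- 0; cnt <- 0
  for (k in frames) {
    vk <- field$v[idx$ix, idx$iy, k, drop = FALSE][, , 1, drop = TRUE]
    if (!is.null(field$mask)) {
      mk <- field$mask[idx$ix, idx$iy, k, drop = FALSE][, , 1, drop = TRUE]
      vk[!mk] <- NA_real_
    }
    dvdx <- (vk[3:nxw, , drop = FALSE] - vk[1:(nxw - 2), , drop = FALSE]) /
      (2 * field$grid$dx)
    acc <- acc + sum(dvdx, na.rm = TRUE)
    cnt <- cnt + sum(is.finite(dvdx))
  }
  acc / cnt
}

#' Normalised mean velocity gradient P~
#'
#' The shear strength of a case normalised by the pure-shear reference:
#' `P~ = P_case / P_pure`. `P~ > 1` means the background shear was
#' intensified, `P~ < 1` attenuated.
#'
#' @param P_case,P_pure Mean gradients (1/s); `P_pure` must be nonzero.
#' @return Dimensionless ratio.
#' @export
normalized_gradient <- function(P_case, P_pure) {
  if (!is.finite(P_pure) || P_pure == 0)
    stop("normalized_gradient: pure-shear reference gradient is zero or undefined")
  P_case / P_pure
}

#' Root-mean-square velocity
#'
#' `sqrt(<u^2 + v^2>)` over the window and frames (spatiotemporal mean).
#'
#' @inheritParams v_profile
#' @return RMS speed in cm/s.
#' @export
rms_velocity <- function(field, window = NULL, frames = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  idx <- window_indices(field$grid, window)
  if (is.null(frames)) frames <- seq_along(field$times)
  u <- field$u[idx$ix, idx$iy, frames, drop = FALSE]
  v <- field$v[idx$ix, idx$iy, frames, drop = FALSE]
  sq <- u^2 + v^2
  if (!is.null(field$mask)) {
    m <- field$mask[idx$ix, idx$iy, frames, drop = FALSE]
    sq[!m] <- NA_real_
  }
  sqrt(mean(sq, na.rm = TRUE))
}

#' Shear diagnostics bundle
#'
#' Collects the streamwise-averaged profile, mean gradient `P`, the
#' normalised gradient `P~` (when a pure-shear reference field or gradient
#' is supplied), and the rms velocity for one case.
#'
#' @param field A [velocity_field()].
#' @param window Optional analysis window (list with `xlim`/`ylim`).
#' @param reference Optional pure-shear reference: a [velocity_field()] or
#'   a numeric `P_pure`.
#' @param frames Optional frame indices to include.
#' @param label Case label carried into reports.
#' @return An object of class `shear_diagnostics`.
#' @export
shear_diagnostics <- function(field, window = NULL, reference = NULL,
                              frames = NULL, label = "case") {
  P <- mean_gradient(field, window, frames)
  P_pure <- if (inherits(reference, "velocity_field"))
    mean_gradient(reference, window, frames) else reference
  structure(list(label = label,
                 profile = v_profile(field, window, frames),
                 P = P,
                 P_tilde = if (is.null(P_pure)) NA_real_
                           else normalized_gradient(P, P_pure),
                 u_rms = rms_velocity(field, window, frames),
                 window = window,
                 n_frames = length(if (is.null(frames)) field$times else frames)),
            class = "shear_diagnostics")
}

#' @export
print.shear_diagnostics <- function(x, ...) {
  cat(sprintf("<shear_diagnostics> %s: P = %.4g 1/s%s, u_rms = %.4g cm/s (%d frames)\n",
              x$label, x$P,
              if (is.na(x$P_tilde)) "" else sprintf(", P~ = %.3f", x$P_tilde),
              x$u_rms, x$n_frames))
  invisible(x)
}
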