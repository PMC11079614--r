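#' Regular 2-D analysis grid
#'
#' Node-centred rectangular grid in CGS units. `x` is the cross-stream
#' coordinate and `y` the streamwise coordinate; node `(i, j)` (1-based)
#' sits at physical position `(x0 + (i-1)*dx, y0 + (j-1)*dy)`.
#'
#' @param nx,ny Number of nodes along x and y (each at least 4).
#' @param dx,dy Node spacing in cm (positive).
#' @param x0,y0 Physical coordinate of node (1, 1) in cm.
#' @return An object of class `grid2d`.
#' @export
grid2d <- function(nx, ny, dx, dy = dx, x0 = 0, y0 = 0) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4L || ny < 4L) stop("grid2d: nx and ny must each be >= 4")
  if (!(dx > 0) || !(dy > 0)) stop("grid2d: dx and dy must be positive")
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 x0 = as.numeric(x0), y0 = as.numeric(y0)),
            class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d nodes, dx = %g cm, dy = %g cm, origin (%g, %g) cm\n",
              x$nx, x$ny, x$dx, x$dy, x$x0, x$y0))
  invisible(x)
}

#' Node coordinates of a grid
#'
#' @param grid A [grid2d()].
#' @return A list with numeric vectors `x` (length `nx`) and `y` (length `ny`).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid2d"))
  list(x = grid$x0 + (seq_len(grid$nx) - 1) * grid$dx,
       y = grid$y0 + (seq_len(grid$ny) - 1) * grid$dy)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol &&
    abs(a$x0 - b$x0) < tol && abs(a$y0 - b$y0) < tol
}

as_field_array <- function(a, grid, nt, what) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(sprintf("%s must be an nx x ny x nt array", what))
  if (!all(dim(a) == c(grid$nx, grid$ny, nt)))
    stop(sprintf("%s has dim (%s); expected (%d, %d, %d)", what,
                 paste(dim(a), collapse = ", "), grid$nx, grid$ny, nt))
  storage.mode(a) <- "double"
  a
}

#' Time-resolved 2-D velocity field
#'
#' The container every analysis stage consumes and produces: velocity
#' components on the nodes of a [grid2d()], for one or more time instants.
#' Components are stored as `nx x ny x nt` arrays, first index along x.
#' An optional logical mask marks valid nodes (e.g. a premasked swimmer
#' body); invalid nodes are excluded from spatial averages downstream and
#' handled by normalised convolution during filtering.
#'
#' @param grid A [grid2d()].
#' @param times Strictly increasing time instants in seconds.
#' @param u,v Velocity components (cm/s), `nx x ny x nt` arrays (a matrix is
#'   accepted for a single frame).
#' @param mask Optional logical array of the same shape; `TRUE` = valid.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(grid, times, u, v, mask = NULL) {
  stopifnot(inherits(grid, "grid2d"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("velocity_field: times must be non-empty and strictly increasing")
  nt <- length(times)
  u <- as_field_array(u, grid, nt, "u")
  v <- as_field_array(v, grid, nt, "v")
  if (!is.null(mask)) {
    if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
    if (!all(dim(mask) == dim(u))) stop("velocity_field: mask shape mismatch")
    mask <- array(as.logical(mask), dim = dim(u))
    if (any(!is.finite(u[mask])) || any(!is.finite(v[mask])))
      stop("velocity_field: non-finite velocity inside the valid mask")
  } else {
    if (any(!is.finite(u)) || any(!is.finite(v)))
      stop("velocity_field: non-finite velocity values (supply a mask to mark invalid nodes)")
  }
  structure(list(grid = grid, times = times, u = u, v = v, mask = mask,
                 units = list(length = "cm", time = "s", velocity = "cm/s"),
                 attrs = list()),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d frame(s) on %d x %d grid (dx = %g cm), t in [%g, %g] s\n",
              length(x$times), x$grid$nx, x$grid$ny, x$grid$dx,
              min(x$times), max(x$times)))
  sp <- field_speed(x)
  cat(sprintf("  speed: rms %.4g cm/s, max %.4g cm/s%s\n",
              sqrt(mean(sp^2, na.rm = TRUE)), max(sp, na.rm = TRUE),
              if (is.null(x$mask)) "" else
                sprintf("; %.1f%% nodes masked invalid", 100 * mean(!x$mask))))
  invisible(x)
}

field_speed <- function(field) {
  sp <- sqrt(field$u^2 + field$v^2)
  if (!is.null(field$mask)) sp[!field$mask] <- NA_real_
  sp
}

#' Scalar field on a 2-D grid
#'
#' Holds per-node scalars such as the pointwise energy-flux density
#' Q (cm^2/s^3) or the filtered kinetic energy.
#'
#' @param grid A [grid2d()].
#' @param times Time instants (s).
#' @param values `nx x ny x nt` array (matrix accepted for one frame).
#' @param units Unit string recorded as metadata.
#' @param attrs Optional named list of metadata (e.g. kernel, L).
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(grid, times, values, units = "", attrs = list()) {
  stopifnot(inherits(grid, "grid2d"))
  times <- as.numeric(times)
  values <- as_field_array(values, grid, length(times), "values")
  structure(list(grid = grid, times = times, values = values,
                 units = units, attrs = attrs),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d frame(s) on %d x %d grid%s; mean %.4g, sd %.4g\n",
              length(x$times), x$grid$nx, x$grid$ny,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              mean(x$values, na.rm = TRUE), stats::sd(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Symmetric 2-D tensor field
#'
#' Stores the three independent components of a symmetric 2x2 tensor per
#' node and frame: `txx`, `txy`, `tyy`. Used for turbulent stresses
#' (cm^2/s^2) and rate-of-strain tensors (1/s). Symmetry is structural —
#' only three components exist.
#'
#' @param grid A [grid2d()].
#' @param times Time instants (s).
#' @param txx,txy,tyy Component arrays, `nx x ny x nt`.
#' @param units Unit string.
#' @param attrs Metadata list; filtering stages record `kernel` and `L` here.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(grid, times, txx, txy, tyy, units = "", attrs = list()) {
  stopifnot(inherits(grid, "grid2d"))
  times <- as.numeric(times)
  nt <- length(times)
  structure(list(grid = grid, times = times,
                 txx = as_field_array(txx, grid, nt, "txx"),
                 txy = as_field_array(txy, grid, nt, "txy"),
                 tyy = as_field_array(tyy, grid, nt, "tyy"),
                 units = units, attrs = attrs),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  nrm <- sqrt(x$txx^2 + 2 * x$txy^2 + x$tyy^2)
  cat(sprintf("<tensor_field> %d frame(s) on %d x %d grid%s; rms norm %.4g\n",
              length(x$times), x$grid$nx, x$grid$ny,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              sqrt(mean(nrm^2, na.rm = TRUE))))
  invisible(x)
}

#' Crop a velocity field to a physical window
#'
#' Returns the sub-field whose node coordinates fall inside the closed
#' ranges, with identical spacing. A small tolerance (1e-9 of the spacing)
#' guards against floating-point edges. Used to restrict analysis to the
#' near-jet interrogation window.
#'
#' @param field A [velocity_field()].
#' @param xlim,ylim Length-2 numeric ranges in cm.
#' @return A [velocity_field()] on the cropped grid.
#' @export
crop <- function(field, xlim, ylim) {
  stopifnot(inherits(field, "velocity_field"))
  co <- grid_coords(field$grid)
  tolx <- 1e-9 * field$grid$dx; toly <- 1e-9 * field$grid$dy
  ix <- which(co$x >= min(xlim) - tolx & co$x <= max(xlim) + tolx)
  iy <- which(co$y >= min(ylim) - toly & co$y <= max(ylim) + toly)
  if (length(ix) < 4L || length(iy) < 4L)
    stop("crop: window intersects fewer than 4 nodes along an axis")
  g <- grid2d(length(ix), length(iy), field$grid$dx, field$grid$dy,
              x0 = co$x[ix[1]], y0 = co$y[iy[1]])
  velocity_field(g, field$times,
                 field$u[ix, iy, , drop = FALSE],
                 field$v[ix, iy, , drop = FALSE],
                 if (is.null(field$mask)) NULL else field$mask[ix, iy, , drop = FALSE])
}

#' Superpose velocity fields
#'
#' Nodewise sum of two or more fields sharing one grid and time base.
#' Masks combine with logical AND (a node is valid only where every
#' component field is valid).
#'
#' @param ... Two or more [velocity_field()] objects.
#' @return A [velocity_field()].
#' @export
superpose <- function(...) {
  fields <- list(...)
  if (length(fields) == 1L && is.list(fields[[1]]) &&
      !inherits(fields[[1]], "velocity_field")) fields <- fields[[1]]
  stopifnot(length(fields) >= 1L)
  base <- fields[[1]]
  stopifnot(inherits(base, "velocity_field"))
  u <- base$u; v <- base$v; mask <- base$mask
  for (f in fields[-1]) {
    stopifnot(inherits(f, "velocity_field"))
    if (!same_grid(base$grid, f$grid)) stop("superpose: grid mismatch")
    if (length(f$times) != length(base$times) ||
        any(abs(f$times - base$times) > 1e-9))
      stop("superpose: time base mismatch")
    u <- u + f$u; v <- v + f$v
    if (!is.null(f$mask)) mask <- if (is.null(mask)) f$mask else (mask & f$mask)
  }
  if (!is.null(mask)) { u[!mask] <- 0; v[!mask] <- 0 }
  velocity_field(base$grid, base$times, u, v, mask)
}

#' @export
plot.velocity_field <- function(x, frame = 1L, what = c("speed", "u", "v"), ...) {
  what <- match.arg(what)
  co <- grid_coords(x$grid)
  z <- switch(what, speed = sqrt(x$u[, , frame]^2 + x$v[, , frame]^2),
              u = x$u[, , frame], v = x$v[, , frame])
  graphics::image(co$x, co$y, z, xlab = "x (cm)", ylab = "y (cm)",
                  main = sprintf("%s, t = %g s", what, x$times[frame]),
                  col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.scalar_field <- function(x, frame = 1L, ...) {
  co <- grid_coords(x$grid)
  z <- x$values[, , frame]
  lim <- max(abs(z), na.rm = TRUE)
  graphics::image(co$x, co$y, z, zlim = c(-lim, lim),
                  xlab = "x (cm)", ylab = "y (cm)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), useRaster = TRUE, ...)
  invisible(x)
}
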