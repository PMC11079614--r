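#' PTV acquisition configuration
#'
#' Emulates the laboratory particle-tracking acquisition: about 9,000
#' tracked particles per frame at 60 frames per second over the
#' interrogation window, with isotropic Gaussian position noise (the
#' default noise scale, 0.2 of a grid spacing, is applied at
#' reconstruction-grid resolution).
#'
#' @param particles_per_frame Tracked particle count, default 9000
#'   (at least 100 for reconstruction use).
#' @param frame_rate Frames per second, default 60.
#' @param position_noise_sd Gaussian position noise in cm; `NULL` means
#'   `0.2 * dx` of the advecting field's grid.
#' @param seed Integer seed for seeding positions and noise.
#' @return An object of class `ptv_config`.
#' @export
ptv_config <- function(particles_per_frame = 9000, frame_rate = 60,
                       position_noise_sd = NULL, seed = 1L) {
  if (particles_per_frame < 100)
    stop("ptv_config: at least 100 particles per frame are needed for reconstruction")
  if (!(frame_rate > 0)) stop("ptv_config: frame_rate must be positive")
  if (!is.null(position_noise_sd) && position_noise_sd < 0)
    stop("ptv_config: position_noise_sd must be >= 0")
  structure(list(particles_per_frame = as.integer(particles_per_frame),
                 frame_rate = frame_rate,
                 position_noise_sd = position_noise_sd,
                 seed = as.integer(seed)),
            class = "ptv_config")
}

# bilinear space / linear time sampling of a velocity field at points
interp_velocity <- function(field, px, py, t) {
  g <- field$grid
  nt <- length(field$times)
  if (nt == 1L) {
    ka <- 1L; kb <- 1L; wb <- 0
  } else {
    kb <- findInterval(t, field$times, all.inside = TRUE)
    ka <- kb; kb <- pmin(ka + 1L, nt)
    dt <- field$times[kb] - field$times[ka]
    wb <- ifelse(dt > 0, (t - field$times[ka]) / dt, 0)
    ka <- ka[1]; kb <- kb[1]; wb <- wb[1]  # scalar t expected
  }
  fx <- (px - g$x0) / g$dx; fy <- (py - g$y0) / g$dy
  i <- pmin(pmax(floor(fx), 0), g$nx - 2L); j <- pmin(pmax(floor(fy), 0), g$ny - 2L)
  ax <- fx - i; ay <- fy - j
  i <- i + 1L; j <- j + 1L
  bil <- function(A) {
    k <- ka
    z <- A[cbind(i, j, k)] * (1 - ax) * (1 - ay) +
      A[cbind(i + 1L, j, k)] * ax * (1 - ay) +
      A[cbind(i, j + 1L, k)] * (1 - ax) * ay +
      A[cbind(i + 1L, j + 1L, k)] * ax * ay
    if (wb > 0) {
      k <- kb
      zb <- A[cbind(i, j, k)] * (1 - ax) * (1 - ay) +
        A[cbind(i + 1L, j, k)] * ax * (1 - ay) +
        A[cbind(i, j + 1L, k)] * (1 - ax) * ay +
        A[cbind(i + 1L, j + 1L, k)] * ax * ay
      z <- (1 - wb) * z + wb * zb
    }
    z
  }
  list(u = bil(field$u), v = bil(field$v))
}

#' Emulate particle tracking velocimetry on a velocity field
#'
#' Seeds tracer particles uniformly over the field's domain, advects them
#' through the (time-interpolated) velocity field with classical 4-stage
#' Runge-Kutta at one quarter of the frame interval, samples positions at
#' the frame rate, adds Gaussian position noise, and attaches velocities
#' by central differencing of the recorded (noisy) positions — exactly
#' what a tracking algorithm sees. Particles that leave the domain have
#' their track truncated and are reseeded under a fresh track id.
#'
#' @param field A [velocity_field()] covering the duration.
#' @param config A [ptv_config()].
#' @param duration Recording length in seconds.
#' @return A `particle_tracks` data frame with columns
#'   `track_id, t, x, y, u, v`.
#' @export
emulate_ptv <- function(field, config, duration) {
  stopifnot(inherits(field, "velocity_field"), inherits(config, "ptv_config"))
  g <- field$grid
  co <- grid_coords(g)
  xr <- range(co$x); yr <- range(co$y)
  t0 <- field$times[1]
  if (length(field$times) > 1 && t0 + duration > max(field$times) + 1e-9)
    stop("emulate_ptv: field does not cover the requested duration")
  dt_frame <- 1 / config$frame_rate
  n_frames <- max(2L, floor(duration / dt_frame) + 1L)
  frame_t <- t0 + (seq_len(n_frames) - 1) * dt_frame
  np <- config$particles_per_frame
  noise_sd <- if (is.null(config$position_noise_sd)) 0.2 * g$dx else config$position_noise_sd
  rs <- local_rng(config$seed)
  px <- rs$runif(np, xr[1], xr[2]); py <- rs$runif(np, yr[1], yr[2])
  ids <- seq_len(np); next_id <- np + 1L
  X <- matrix(NA_real_, n_frames, np); Y <- X
  ID <- matrix(NA_integer_, n_frames, np)
  X[1, ] <- px; Y[1, ] <- py; ID[1, ] <- ids
  h <- dt_frame / 4
  for (f in seq_len(n_frames - 1L)) {
    tt <- frame_t[f]
    for (s in 1:4) {
      k1 <- interp_velocity(field, px, py, tt)
      k2 <- interp_velocity(field, px + h / 2 * k1$u, py + h / 2 * k1$v, tt + h / 2)
      k3 <- interp_velocity(field, px + h / 2 * k2$u, py + h / 2 * k2$v, tt + h / 2)
      k4 <- interp_velocity(field, px + h * k3$u, py + h * k3$v, tt + h)
      px <- px + h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
      py <- py + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
      tt <- tt + h
    }
    out_of_domain <- px < xr[1] | px > xr[2] | py < yr[1] | py > yr[2]
    n_out <- sum(out_of_domain)
    if (n_out > 0) {
      px[out_of_domain] <- rs$runif(n_out, xr[1], xr[2])
      py[out_of_domain] <- rs$runif(n_out, yr[1], yr[2])
      ids[out_of_domain] <- seq.int(next_id, length.out = n_out)
      next_id <- next_id + n_out
    }
    X[f + 1L, ] <- px; Y[f + 1L, ] <- py; ID[f + 1L, ] <- ids
  }
  if (noise_sd > 0) {
    X <- X + matrix(rs$rnorm(length(X), sd = noise_sd), nrow(X))
    Y <- Y + matrix(rs$rnorm(length(Y), sd = noise_sd), nrow(Y))
  }
  # central-difference velocities along each column where the id persists
  U <- matrix(NA_real_, n_frames, np); V <- U
  if (n_frames >= 2) {
    same_next <- rbind(ID[-1, , drop = FALSE] == ID[-n_frames, , drop = FALSE], FALSE)
    same_prev <- rbind(FALSE, same_next[-n_frames, , drop = FALSE])
    ctr <- same_next & same_prev
    fwd <- same_next & !same_prev
    bwd <- !same_next & same_prev
    idx <- function(m, off) {
      shifted <- matrix(NA_real_, n_frames, np)
      if (off > 0) shifted[seq_len(n_frames - off), ] <- m[(off + 1):n_frames, ]
      else shifted[(1 - off):n_frames, ] <- m[seq_len(n_frames + off), ]
      shifted
    }
    U[ctr] <- ((idx(X, 1) - idx(X, -1)) / (2 * dt_frame))[ctr]
    V[ctr] <- ((idx(Y, 1) - idx(Y, -1)) / (2 * dt_frame))[ctr]
    U[fwd] <- ((idx(X, 1) - X) / dt_frame)[fwd]
    V[fwd] <- ((idx(Y, 1) - Y) / dt_frame)[fwd]
    U[bwd] <- ((X - idx(X, -1)) / dt_frame)[bwd]
    V[bwd] <- ((Y - idx(Y, -1)) / dt_frame)[bwd]
  }
  keep <- !is.na(U)
  df <- data.frame(track_id = as.integer(ID[keep]),
                   t = rep(frame_t, times = np)[as.vector(keep)],
                   x = X[keep], y = Y[keep], u = U[keep], v = V[keep])
  as_particle_tracks(df)
}

#' Reconstruct an Eulerian velocity field from particle tracks
#'
#' Scattered-to-grid re-gridding of per-frame track velocities by moving
#' weighted least squares: around every grid node, particles within an
#' adaptive radius are fit with a bivariate polynomial (default cubic,
#' matching cubic re-gridding practice) under Gaussian distance weights,
#' and the node value is the fit's value at the node. Nodes without
#' enough support are masked; frames with fewer than 50 samples are masked
#' entirely with a warning.
#'
#' @param tracks A `particle_tracks` data frame with `u`, `v` columns.
#' @param grid Target [grid2d()].
#' @param degree Polynomial degree of the local fit (1-3), default 3.
#' @param radius Initial search radius in cm; default `2.5 * max(dx, dy)`.
#'   Doubled (up to 8x) where support is insufficient.
#' @return A [velocity_field()] on `grid` with a validity mask.
#' @export
reconstruct_field <- function(tracks, grid, degree = 3L, radius = NULL) {
  stopifnot(inherits(tracks, "data.frame"), inherits(grid, "grid2d"))
  if (!all(c("u", "v") %in% names(tracks)))
    stop("reconstruct_field: tracks need u and v columns")
  degree <- as.integer(degree)
  stopifnot(degree >= 1L, degree <= 3L)
  if (is.null(radius)) radius <- 2.5 * max(grid$dx, grid$dy)
  times <- sort(unique(tracks$t))
  nt <- length(times)
  co <- grid_coords(grid)
  u <- array(NA_real_, dim = c(grid$nx, grid$ny, nt)); v <- u
  mask <- array(FALSE, dim = dim(u))
  for (k in seq_len(nt)) {
    sel <- tracks$t == times[k]
    if (sum(sel) < 50L) {
      warning(sprintf("reconstruct_field: frame t = %g has %d samples (< 50); frame masked",
                      times[k], sum(sel)))
      next
    }
    fit <- mwls_frame(tracks$x[sel], tracks$y[sel], tracks$u[sel], tracks$v[sel],
                      co$x, co$y, degree, radius)
    u[, , k] <- fit$u; v[, , k] <- fit$v
    mask[, , k] <- fit$ok
  }
  u[!mask] <- 0; v[!mask] <- 0
  out <- velocity_field(grid, times, u, v, mask)
  out$attrs <- list(source = "ptv_reconstruction", degree = degree,
                    radius = radius)
  out
}

poly_design <- function(xi, eta, degree) {
  cols <- list(rep(1, length(xi)))
  if (degree >= 1) cols <- c(cols, list(xi, eta))
  if (degree >= 2) cols <- c(cols, list(xi^2, xi * eta, eta^2))
  if (degree >= 3) cols <- c(cols, list(xi^3, xi^2 * eta, xi * eta^2, eta^3))
  do.call(cbind, cols)
}

mwls_frame <- function(px, py, pu, pv, xs, ys, degree, radius0) {
  nx <- length(xs); ny <- length(ys)
  ncoef <- c(3L, 6L, 10L)[degree]
  need <- 2L * ncoef
  dx <- if (nx > 1) xs[2] - xs[1] else 1
  dy <- if (ny > 1) ys[2] - ys[1] else 1
  # bin particles into grid cells for fast neighbour gathering
  ci <- pmin(pmax(as.integer(floor((px - xs[1]) / dx)) + 1L, 1L), nx)
  cj <- pmin(pmax(as.integer(floor((py - ys[1]) / dy)) + 1L, 1L), ny)
  cell <- ci + nx * (cj - 1L)
  ord <- order(cell)
  cell_sorted <- cell[ord]
  starts <- c(1L, which(diff(cell_sorted) > 0) + 1L)
  cell_ids <- cell_sorted[starts]
  ends <- c(starts[-1] - 1L, length(cell_sorted))
  lookup <- integer(nx * ny); lookup[cell_ids] <- seq_along(cell_ids)
  gather <- function(i0, i1, j0, j1) {
    cells <- as.vector(outer(i0:i1, (j0:j1 - 1L) * nx, `+`))
    li <- lookup[cells]; li <- li[li > 0L]
    if (!length(li)) return(integer(0))
    unlist(lapply(li, function(q) ord[starts[q]:ends[q]]), use.names = FALSE)
  }
  U <- matrix(NA_real_, nx, ny); V <- U; OK <- matrix(FALSE, nx, ny)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      r <- radius0
      repeat {
        ri <- ceiling(r / dx); rj <- ceiling(r / dy)
        cand <- gather(max(1L, i - ri), min(nx, i + ri),
                       max(1L, j - rj), min(ny, j + rj))
        if (length(cand)) {
          ddx <- px[cand] - xs[i]; ddy <- py[cand] - ys[j]
          inr <- ddx^2 + ddy^2 <= r^2
          cand <- cand[inr]; ddx <- ddx[inr]; ddy <- ddy[inr]
        }
        if (length(cand) >= need || r >= 8 * radius0) break
        r <- 2 * r
      }
      if (length(cand) < need) next
      w <- exp(-(ddx^2 + ddy^2) / (2 * (r / 2)^2))
      A <- poly_design(ddx / r, ddy / r, degree) * sqrt(w)
      qrA <- qr(A)
      if (qrA$rank < ncoef) next
      cu <- qr.coef(qrA, pu[cand] * sqrt(w))
      cv <- qr.coef(qrA, pv[cand] * sqrt(w))
      U[i, j] <- cu[1]; V[i, j] <- cv[1]
      OK[i, j] <- TRUE
    }
  }
  list(u = U, v = V, ok = OK)
}
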