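#' Write a velocity field to disk
#'
#' Three dialects are supported, all self-describing and mutually
#' round-trippable through [read_velocity_field()]:
#' \describe{
#'   \item{`"json"`}{a JSON container carrying dimensions, coordinates,
#'     units and the component arrays — portable across languages.}
#'   \item{`"csv"`}{long-form text, one row per (t, x, y) node with columns
#'     `t,x,y,u,v[,mask]` and grid metadata in `#`-prefixed header lines.}
#'   \item{`"rds"`}{R's native binary serialisation of the object.}
#' }
#' Units are fixed package-wide to CGS (cm, s) and recorded in the file.
#' Non-finite velocities are only permitted at nodes the mask marks
#' invalid.
#'
#' @param field A [velocity_field()].
#' @param path Output file path.
#' @param dialect One of `"json"`, `"csv"`, `"rds"`.
#' @return Invisibly, `path`.
#' @export
write_velocity_field <- function(field, path, dialect = c("json", "csv", "rds")) {
  stopifnot(inherits(field, "velocity_field"))
  dialect <- match.arg(dialect)
  if (!is.null(field$mask) &&
      (any(!is.finite(field$u[field$mask])) || any(!is.finite(field$v[field$mask]))))
    stop("write_velocity_field: non-finite velocity inside the valid mask")
  g <- field$grid
  if (dialect == "rds") {
    saveRDS(field, path)
    return(invisible(path))
  }
  if (dialect == "json") {
    obj <- list(
      format = "fstflux-velocity-field", version = 1L,
      units = field$units,
      grid = list(nx = g$nx, ny = g$ny, dx = g$dx, dy = g$dy, x0 = g$x0, y0 = g$y0),
      n_times = length(field$times),
      times = field$times,
      # arrays flattened in R (column-major) order over (x, y, t)
      u = as.numeric(field$u), v = as.numeric(field$v),
      mask = if (is.null(field$mask)) NULL else as.integer(field$mask),
      attrs = field$attrs)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  # long-form CSV
  co <- grid_coords(g)
  nt <- length(field$times)
  df <- data.frame(
    t = rep(field$times, each = g$nx * g$ny),
    x = rep(co$x, times = g$ny * nt),
    y = rep(rep(co$y, each = g$nx), times = nt),
    u = as.numeric(field$u), v = as.numeric(field$v))
  if (!is.null(field$mask)) df$mask <- as.integer(field$mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fstflux-velocity-field csv v1",
               sprintf("# grid nx=%d ny=%d dx=%.15g dy=%.15g x0=%.15g y0=%.15g",
                       g$nx, g$ny, g$dx, g$dy, g$x0, g$y0),
               sprintf("# n_times=%d units=cm,s,cm/s", nt)), con)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a velocity field from disk
#'
#' Counterpart of [write_velocity_field()]. The CSV reader infers the grid
#' from the data when header metadata is absent, requires uniform spacing
#' (relative tolerance 1e-6) and reports any missing (x, y) node by its
#' coordinates.
#'
#' @param path Input file.
#' @param dialect One of `"json"`, `"csv"`, `"rds"`; default guesses from
#'   the file extension.
#' @return A [velocity_field()].
#' @export
read_velocity_field <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("read_velocity_field: no such file: ", path)
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      json = "json", csv = "csv", rds = "rds",
                      stop("read_velocity_field: cannot guess dialect from extension"))
  }
  dialect <- match.arg(dialect, c("json", "csv", "rds"))
  if (dialect == "rds") {
    field <- readRDS(path)
    if (!inherits(field, "velocity_field"))
      stop("read_velocity_field: RDS file does not contain a velocity_field")
    return(field)
  }
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$format) || obj$format != "fstflux-velocity-field")
      stop("read_velocity_field: not an fstflux velocity-field JSON file")
    gg <- obj$grid
    if (any(!c("nx", "ny", "dx", "dy", "x0", "y0") %in% names(gg)))
      stop("read_velocity_field: format error — grid metadata incomplete")
    g <- grid2d(gg$nx, gg$ny, gg$dx, gg$dy, gg$x0, gg$y0)
    nt <- length(obj$times)
    dims <- c(g$nx, g$ny, nt)
    mask <- if (!is.null(obj$mask)) array(obj$mask > 0, dim = dims) else NULL
    f <- velocity_field(g, obj$times,
                        array(obj$u, dim = dims), array(obj$v, dim = dims), mask)
    if (!is.null(obj$attrs) && length(obj$attrs)) f$attrs <- as.list(obj$attrs)
    return(f)
  }
  read_velocity_csv(path)
}

uniform_axis <- function(vals, what) {
  s <- sort(unique(vals))
  if (length(s) < 2L) stop("velocity CSV: degenerate ", what, " axis")
  d <- diff(s)
  if ((max(d) - min(d)) > 1e-6 * mean(d))
    stop("velocity CSV: non-uniform ", what, " spacing (beyond 1e-6 relative tolerance)")
  s
}

read_velocity_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "x", "y", "u", "v")
  if (!all(need %in% names(df)))
    stop("velocity CSV: format error — need columns ", paste(need, collapse = ","))
  xs <- uniform_axis(df$x, "x"); ys <- uniform_axis(df$y, "y")
  ts <- sort(unique(df$t))
  nx <- length(xs); ny <- length(ys); nt <- length(ts)
  if (nrow(df) != nx * ny * nt) {
    # locate a hole for the error message
    key <- expand.grid(x = xs, y = ys)
    have <- unique(paste(signif(df$x, 12), signif(df$y, 12)))
    want <- paste(signif(key$x, 12), signif(key$y, 12))
    miss <- which(!(want %in% have))[1]
    stop(sprintf("velocity CSV: format error — missing node at (x = %g, y = %g)",
                 key$x[miss], key$y[miss]))
  }
  ix <- match_axis(df$x, xs); iy <- match_axis(df$y, ys); it <- match_axis(df$t, ts)
  idx <- ix + nx * (iy - 1L) + nx * ny * (it - 1L)
  if (anyDuplicated(idx)) stop("velocity CSV: duplicate (t, x, y) rows")
  u <- array(NA_real_, dim = c(nx, ny, nt)); v <- u
  u[idx] <- df$u; v[idx] <- df$v
  mask <- NULL
  if ("mask" %in% names(df)) {
    mask <- array(FALSE, dim = c(nx, ny, nt)); mask[idx] <- df$mask > 0
    u[!mask & !is.finite(u)] <- 0; v[!mask & !is.finite(v)] <- 0
  }
  g <- grid2d(nx, ny, mean(diff(xs)), mean(diff(ys)), xs[1], ys[1])
  velocity_field(g, ts, u, v, mask)
}

# nearest-node lookup; handles the (possibly irregular) time axis too
match_axis <- function(vals, axis) {
  i <- findInterval(vals, axis)
  i[i < 1L] <- 1L
  ip <- pmin(i + 1L, length(axis))
  ifelse(abs(axis[ip] - vals) < abs(axis[i] - vals), ip, i)
}

#' Read particle tracks
#'
#' Reads a CSV with header `track_id,t,x,y[,u,v]` into a canonical
#' track table sorted by (track_id, t). Duplicate `(track_id, t)` pairs and
#' non-monotone times within a track are format errors naming the track.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `particle_tracks`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("read_tracks: no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  as_particle_tracks(df)
}

#' Coerce a data frame to a canonical particle-track set
#'
#' @param df Data frame with columns `track_id,t,x,y` and optionally `u,v`.
#' @return A `data.frame` of class `particle_tracks`, sorted by (track_id, t).
#' @export
as_particle_tracks <- function(df) {
  need <- c("track_id", "t", "x", "y")
  if (!all(need %in% names(df)))
    stop("particle tracks: need columns ", paste(need, collapse = ","))
  df <- df[order(df$track_id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  dup <- duplicated(df[, c("track_id", "t")])
  if (any(dup))
    stop("particle tracks: duplicate (track_id, t) record in track ",
         df$track_id[which(dup)[1]])
  dt <- stats::ave(df$t, df$track_id, FUN = function(z) c(1, diff(z)))
  if (any(dt <= 0))
    stop("particle tracks: non-increasing time within track ",
         df$track_id[which(dt <= 0)[1]])
  class(df) <- c("particle_tracks", "data.frame")
  df
}

#' Write particle tracks
#'
#' @param tracks A `particle_tracks` data frame (see [read_tracks()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "data.frame"))
  df <- as.data.frame(tracks)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
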