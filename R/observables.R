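#' Normalized angular momentum
#'
#' The vortex order parameter: the per-agent average of the z-component of
#' `r x v` divided by `|r|`, with positions measured from the arena centre,
#'
#'   L = (1/N) * sum_i (x_i vy_i - y_i vx_i) / |r_i|.
#'
#' Dividing by `|r_i|` makes every agent contribute equally irrespective of
#' its distance to the centre, leaving L in speed units (m/s); positive L is
#' counterclockwise rotation. Each summand is bounded by the agent's speed,
#' so `|L| <= max_i |v_i|`.
#'
#' @param positions N x 2 positions (relative to `center`), m.
#' @param velocities N x 2 velocities, m/s.
#' @param center Length-2 origin of the rotation measure (arena centre).
#' @param normalized Divide each term by `|r_i|` (default). `FALSE` gives
#'   the unnormalized variant `(1/N) sum (r x v)_z` used as a robustness
#'   check; results are qualitatively insensitive to this choice.
#' @return Scalar L, m/s (m^2/s if `normalized = FALSE`).
#' @examples
#' # four agents on a unit circle moving tangentially CCW at 1 m/s
#' p <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
#' v <- rbind(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
#' angular_momentum(p, v)  # 1
#' @export
angular_momentum <- function(positions, velocities, center = c(0, 0),
                             normalized = TRUE) {
  p <- as_xy_matrix(positions)
  v <- as_xy_matrix(velocities)
  stopifnot(nrow(p) >= 1L, nrow(p) == nrow(v))
  rx <- p[, 1] - center[1]
  ry <- p[, 2] - center[2]
  cross <- rx * v[, 2] - ry * v[, 1]
  if (normalized) {
    r <- sqrt(rx^2 + ry^2)
    if (any(r == 0)) stop("agent exactly at the centre: |r| = 0")
    cross <- cross / r
  }
  mean(cross)
}

#' Angular momentum time series
#'
#' Evaluates [angular_momentum()] at every recorded frame of a trajectory.
#'
#' @param traj A `ped_trajectory`.
#' @inheritParams angular_momentum
#' @return An `l_series` object: data.table with columns `t` and `L`, with
#'   `n_agents` attached as an attribute.
#' @export
l_series <- function(traj, center = c(0, 0), normalized = TRUE) {
  x <- NULL; y <- NULL; vx <- NULL; vy <- NULL  # NSE columns
  out <- traj[, list(L = angular_momentum(cbind(x, y), cbind(vx, vy),
                                          center, normalized)),
              by = t]
  data.table::setattr(out, "n_agents", length(unique(traj$agent_id)))
  data.table::setattr(out, "class", unique(c("l_series", class(out))))
  out
}

#' Burn-in-excluded time average of L
#'
#' Arithmetic mean of L(t) over frames with `t > burn_in`, the per-run
#' summary used in bifurcation diagrams and phase-space maps.
#'
#' @param series An [l_series()] result (or any table with `t`, `L`).
#' @param burn_in Initial interval to exclude, s.
#' @return Scalar mean L.
#' @export
time_avg_L <- function(series, burn_in = 200) {
  keep <- series$t > burn_in
  if (!any(keep)) stop("no frames after the burn-in window")
  mean(series$L[keep])
}

#' Coarse-grained density and velocity fields
#'
#' Spreads each agent over a uniform disc ("Heaviside") kernel
#' `H(omega - |r - r_i|) / (pi omega^2)` of radius `omega = 0.25` m, about
#' the physical size of one person, and averages over recorded frames after
#' the burn-in. The instantaneous density integrates to N by construction;
#' the speed and velocity fields are occupancy-weighted kernel means (cells
#' never covered by any agent get NA).
#'
#' @param traj A `ped_trajectory`.
#' @param omega Kernel radius, m.
#' @param grid_spacing Cell size of the evaluation grid, m.
#' @param burn_in Frames with `t <= burn_in` are ignored.
#' @param arena Arena defining the grid extent; taken from the trajectory
#'   attributes by default.
#' @return A `field_grid` list: `x`, `y` cell-centre coordinates, matrices
#'   `density` (persons/m^2), `speed` (m/s), `vx_mean`, `vy_mean`, plus
#'   `omega` and `grid_spacing`.
#' @export
coarse_grain_fields <- function(traj, omega = 0.25, grid_spacing = 0.1,
                                burn_in = 0, arena = NULL) {
  stopifnot(omega > 0, grid_spacing > 0)
  if (is.null(arena)) arena <- attr(traj, "arena")
  if (is.null(arena)) arena <- pedvortex::arena()
  gx <- seq(-arena$width / 2 + grid_spacing / 2, arena$width / 2, by = grid_spacing)
  gy <- seq(-arena$height / 2 + grid_spacing / 2, arena$height / 2, by = grid_spacing)
  nx <- length(gx); ny <- length(gy)
  times <- unique(traj$t)
  if (burn_in > 0) times <- times[times > burn_in]
  if (!length(times)) stop("no frames after the burn-in window")
  kern <- 1 / (pi * omega^2)

  dens <- matrix(0, nx, ny)
  flux <- 0      # sum over frames/agents of kernel weight (occupancy)
  sp_sum <- matrix(0, nx, ny)
  vx_sum <- matrix(0, nx, ny)
  vy_sum <- matrix(0, nx, ny)
  occ <- matrix(0, nx, ny)

  sub <- if (burn_in > 0) traj[traj$t > burn_in] else traj
  for (tt in times) {
    fr <- sub[abs(sub$t - tt) < 1e-9]
    for (k in seq_len(nrow(fr))) {
      # only grid cells within omega of the agent are touched
      ix <- which(abs(gx - fr$x[k]) <= omega)
      iy <- which(abs(gy - fr$y[k]) <= omega)
      if (!length(ix) || !length(iy)) next
      d2 <- outer((gx[ix] - fr$x[k])^2, (gy[iy] - fr$y[k])^2, `+`)
      hit <- d2 <= omega^2
      if (!any(hit)) next
      w <- kern * hit
      dens[ix, iy] <- dens[ix, iy] + w
      spd <- sqrt(fr$vx[k]^2 + fr$vy[k]^2)
      sp_sum[ix, iy] <- sp_sum[ix, iy] + w * spd
      vx_sum[ix, iy] <- vx_sum[ix, iy] + w * fr$vx[k]
      vy_sum[ix, iy] <- vy_sum[ix, iy] + w * fr$vy[k]
      occ[ix, iy] <- occ[ix, iy] + w
    }
  }
  nt <- length(times)
  covered <- occ > 0
  speed <- vx_mean <- vy_mean <- matrix(NA_real_, nx, ny)
  speed[covered] <- sp_sum[covered] / occ[covered]
  vx_mean[covered] <- vx_sum[covered] / occ[covered]
  vy_mean[covered] <- vy_sum[covered] / occ[covered]
  structure(list(x = gx, y = gy, density = dens / nt, speed = speed,
                 vx_mean = vx_mean, vy_mean = vy_mean,
                 omega = omega, grid_spacing = grid_spacing,
                 n_frames = nt),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf(
    "<field_grid> %d x %d cells (spacing %.3g m), kernel omega %.3g m, %d frames\n",
    length(x$x), length(x$y), x$grid_spacing, x$omega, x$n_frames))
  invisible(x)
}

#' Write a field grid as plain-text matrices
#'
#' One file per field (`<stem>_density.txt`, `<stem>_speed.txt`, ...), each
#' a whitespace-separated matrix preceded by `#` header lines recording the
#' grid origin and spacing.
#'
#' @param grid A [coarse_grain_fields()] result.
#' @param stem Output path stem.
#' @return The written file paths, invisibly.
#' @export
write_fields <- function(grid, stem) {
  paths <- character(0)
  for (nm in c("density", "speed", "vx_mean", "vy_mean")) {
    path <- paste0(stem, "_", nm, ".txt")
    con <- file(path, "w")
    writeLines(c(
      sprintf("# field: %s", nm),
      sprintf("# x0: %.6f  y0: %.6f  spacing: %.6f", grid$x[1], grid$y[1],
              grid$grid_spacing),
      sprintf("# omega: %.6f  n_frames: %d", grid$omega, grid$n_frames)), con)
    utils::write.table(grid[[nm]], con, row.names = FALSE, col.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Sliding-window velocity estimates
#'
#' Estimates velocities from positions sampled at a fixed frame rate by a
#' central difference over a sliding window (default 0.76 s), long enough
#' that tracked pedestrians have moved a reasonable distance, which
#' suppresses frame-to-frame tracking jitter. Endpoints use one-sided
#' forward/backward differences over a window of the same length.
#'
#' @param traj A trajectory table (columns `t`, `agent_id`, `x`, `y`) with
#'   uniform frame spacing per agent.
#' @param window Window length, s.
#' @return The table with `vx`, `vy` replaced by the windowed estimates.
#' @export
sliding_velocities <- function(traj, window = 0.76) {
  est_one <- function(t, x, y) {
    nt <- length(t)
    if (nt < 2) stop("track too short for velocity estimation")
    dtf <- diff(t)
    if (max(dtf) - min(dtf) > 1e-6) stop("non-uniform frame spacing")
    dtf <- dtf[1]
    if (dtf > window / 2) stop("frame spacing exceeds window/2")
    h <- max(1L, as.integer(round((window / 2) / dtf)))
    if (2L * h + 1L > nt) stop("track shorter than the velocity window")
    idx <- seq_len(nt)
    lo <- idx - h
    hi <- idx + h
    # one-sided windows of the same total length at the ends
    shift <- pmax(0L, 1L - lo) - pmax(0L, hi - nt)
    lo <- lo + shift
    hi <- hi + shift
    w_eff <- (hi - lo) * dtf
    list(vx = (x[hi] - x[lo]) / w_eff, vy = (y[hi] - y[lo]) / w_eff)
  }
  x <- NULL; y <- NULL  # NSE columns
  out <- data.table::copy(data.table::as.data.table(traj))
  out[, c("vx", "vy") := est_one(t, x, y), by = "agent_id"]
  if (inherits(traj, "ped_trajectory")) {
    out <- new_trajectory(out, config = attr(traj, "config"),
                          params = attr(traj, "params"),
                          arena = attr(traj, "arena"))
  }
  out
}
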