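#' Synthetic trajectory fixtures with known observables
#'
#' Generates analytic trajectories whose ground-truth observables are known
#' exactly, attached as the `truth` attribute. These are the cross-module
#' regression net: every fixture's stored truth must match the observables
#' computed from the table.
#'
#' Kinds:
#' * `rotating_ring`: `n_agents` equally spaced on a circle of `radius`,
#'   moving tangentially at `speed` in `direction` (+1 CCW / -1 CW); truth
#'   `L = direction * speed`.
#' * `radial_burst`: agents moving radially outward at `speed`; truth
#'   `L = 0`.
#' * `wall_approach`: a lone agent walking at the north wall at signed
#'   incidence `alpha_deg`, then turning `turn` ("CCW"/"CW") along a
#'   circular arc and walking off parallel to the wall; constructed to
#'   satisfy all four turn-eligibility conditions exactly once.
#' * `jittered_static`: static positions with uniform per-frame position
#'   jitter of amplitude `jitter` and no velocity columns (tracking-noise
#'   emulation for [sliding_velocities()]).
#'
#' @param kind Fixture kind.
#' @param n_agents Agents (ring/burst/static).
#' @param radius Ring radius or burst start radius, m.
#' @param speed Agent speed, m/s.
#' @param direction +1 (CCW) or -1 (CW), ring only.
#' @param alpha_deg Signed incidence angle, degrees (wall_approach).
#' @param turn "CCW" or "CW" (wall_approach).
#' @param jitter Jitter amplitude, m (jittered_static).
#' @param duration Length, s.
#' @param frame_rate Frames per second (tracking cameras run at 25 fps).
#' @param seed RNG seed (jittered_static).
#' @param arena An [arena()].
#' @return A `ped_trajectory` with a `truth` attribute.
#' @examples
#' tr <- make_fixture("rotating_ring", n_agents = 6, radius = 2, speed = 1)
#' attr(tr, "truth")$L  # 1
#' @export
make_fixture <- function(kind = c("rotating_ring", "radial_burst",
                                  "wall_approach", "jittered_static"),
                         n_agents = 8, radius = 2, speed = 1, direction = 1,
                         alpha_deg = 0, turn = c("CCW", "CW"), jitter = 0.01,
                         duration = NULL, frame_rate = 25, seed = 1L,
                         arena = pedvortex::arena()) {
  kind <- match.arg(kind)
  turn <- match.arg(turn)
  switch(kind,
    rotating_ring = fixture_ring(n_agents, radius, speed, direction,
                                 duration %||% 10, frame_rate, arena),
    radial_burst = fixture_burst(n_agents, radius, speed,
                                 duration %||% 2, frame_rate, arena),
    wall_approach = fixture_wall_approach(alpha_deg, turn, speed,
                                          duration %||% 6, frame_rate, arena),
    jittered_static = fixture_jitter(n_agents, jitter, duration %||% 4,
                                     frame_rate, seed, arena))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_frame_times <- function(duration, frame_rate) {
  seq(0, duration, by = 1 / frame_rate)
}

fixture_table <- function(times, pos_fun, vel_fun, n, arena, truth) {
  n_rec <- length(times)
  rows <- lapply(seq_along(times), function(fi) {
    p <- pos_fun(times[fi])
    v <- vel_fun(times[fi])
    data.table::data.table(t = times[fi], agent_id = seq_len(n),
                           x = p[, 1], y = p[, 2],
                           vx = v[, 1], vy = v[, 2],
                           chirality = NA_integer_)
  })
  out <- data.table::rbindlist(rows)
  if (!all(inside_arena(cbind(out$x, out$y), arena))) {
    stop("fixture kinematics leave the arena")
  }
  new_trajectory(out, arena = arena, truth = truth)
}

fixture_ring <- function(n, radius, speed, direction, duration, frame_rate, arena) {
  stopifnot(direction %in% c(-1, 1), radius > 0, speed > 0)
  phase0 <- 2 * pi * (seq_len(n) - 1) / n
  omega <- direction * speed / radius
  fixture_table(
    fixture_frame_times(duration, frame_rate),
    function(t) radius * cbind(cos(phase0 + omega * t), sin(phase0 + omega * t)),
    function(t) speed * direction *
      cbind(-sin(phase0 + omega * t), cos(phase0 + omega * t)),
    n, arena,
    truth = list(kind = "rotating_ring", L = direction * speed, speed = speed))
}

fixture_burst <- function(n, radius, speed, duration, frame_rate, arena) {
  phase0 <- 2 * pi * (seq_len(n) - 1) / n + 0.3
  u <- cbind(cos(phase0), sin(phase0))
  fixture_table(
    fixture_frame_times(duration, frame_rate),
    function(t) (radius + speed * t) * u,
    function(t) speed * u,
    n, arena,
    truth = list(kind = "radial_burst", L = 0, speed = speed))
}

rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                         sin(a) * v[1] + cos(a) * v[2])

fixture_wall_approach <- function(alpha_deg, turn, speed, duration,
                                  frame_rate, arena) {
  stopifnot(abs(alpha_deg) < 45)
  hh <- arena$height / 2
  a_rad <- alpha_deg * pi / 180
  # velocity direction: perpendicular approach (0, 1) rotated clockwise by
  # alpha, so alpha > 0 points to the right of the approach
  u0 <- rot2(c(0, 1), -a_rad)
  d0 <- 4.0           # start 4 m from the north wall
  d_turn <- 1.2       # begin the arc 1.2 m from the wall
  r_arc <- 0.8        # turn radius, m
  arc_angle <- 100 * pi / 180
  sgn <- if (turn == "CCW") 1 else -1

  p0 <- c(-0.5 * sgn, hh - d0)
  t1 <- (d0 - d_turn) / (speed * u0[2])
  p1 <- p0 + speed * t1 * u0
  centre <- p1 + r_arc * sgn * c(-u0[2], u0[1])   # left/right of the heading
  omega_t <- sgn * speed / r_arc
  t2 <- t1 + arc_angle / (speed / r_arc)
  p2 <- centre + rot2(p1 - centre, omega_t * (t2 - t1))
  u2 <- rot2(u0, sgn * arc_angle)

  pos_fun <- function(t) {
    p <- if (t <= t1) {
      p0 + speed * t * u0
    } else if (t <= t2) {
      centre + rot2(p1 - centre, omega_t * (t - t1))
    } else {
      p2 + speed * (t - t2) * u2
    }
    matrix(p, 1, 2)
  }
  vel_fun <- function(t) {
    v <- if (t <= t1) u0
         else if (t <= t2) rot2(u0, omega_t * (t - t1))
         else u2
    matrix(speed * v, 1, 2)
  }
  fixture_table(
    fixture_frame_times(duration, frame_rate), pos_fun, vel_fun, 1L, arena,
    truth = list(kind = "wall_approach", n_events = 1L, label = turn,
                 wall_id = "N", alpha_deg = alpha_deg))
}

fixture_jitter <- function(n, jitter, duration, frame_rate, seed, arena) {
  with_local_seed(seed, function() {
    base <- cbind(stats::runif(n, -arena$width / 2 + 1, arena$width / 2 - 1),
                  stats::runif(n, -arena$height / 2 + 1, arena$height / 2 - 1))
    times <- fixture_frame_times(duration, frame_rate)
    rows <- lapply(times, function(tt) {
      data.table::data.table(
        t = tt, agent_id = seq_len(n),
        x = base[, 1] + stats::runif(n, -jitter, jitter),
        y = base[, 2] + stats::runif(n, -jitter, jitter))
    })
    out <- data.table::rbindlist(rows)
    # worst case: each coordinate jumps by 2*jitter across the effective
    # window (conservatively 2*floor(w/2 * fr)/fr frames); components add in 2D
    out <- new_trajectory(out, arena = arena,
                          truth = list(kind = "jittered_static", jitter = jitter,
                                       max_speed_bound = sqrt(2) * 2 * jitter /
                                         (2 * floor(0.76 / 2 * frame_rate) / frame_rate)))
    data.table::setattr(out, "positions_only", TRUE)
    out
  })
}

#' Mirror pair of a fixture
#'
#' Returns a fixture together with its reflection about the x-axis; the two
#' angular-momentum series are exact negations and turn labels are swapped.
#'
#' @param ... Passed to [make_fixture()].
#' @return List with elements `original` and `mirrored`.
#' @export
make_mirror_pair <- function(...) {
  orig <- make_fixture(...)
  list(original = orig, mirrored = mirror_trajectory(orig))
}
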