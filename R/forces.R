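#' Force laws
#'
#' Pure reference implementations of the four force laws acting on each
#' agent. The compiled integrator re-implements the same arithmetic for
#' speed; the test suite asserts the two agree.
#'
#' * Propulsion: `mu * (v_d - |v|) * v_hat`, a relaxation toward the desired
#'   speed along the current moving direction `v_hat`.
#' * Agent-agent repulsion: long-range exponential
#'   `A_p * exp(-(r_ij - 2 r0)/B_p)` for `r_ij > 2 r0` (social distancing),
#'   Hertzian contact `eps * (1 - r_ij/(2 r0))^(3/2)` otherwise, both along
#'   the centre line from j to i.
#' * Wall repulsion: `[A_w1 * exp(-(r_iw - r0)/B_w) - gamma * v_n] * n_hat`
#'   for `r_iw > r0` (the damping term only within `damping_range` of the
#'   wall surface), Hertzian `eps * (1 - r_iw/r0)^(3/2) * n_hat` otherwise,
#'   where `n_hat` is the inward wall normal and `v_n = v . n_hat`.
#' * Turning force: `A_w2 * exp(-(r_iw - r0)/B_w) * cos(alpha) * t_hat`
#'   while the agent moves toward the wall (`|alpha| < 90` degrees, `alpha`
#'   the angle between the moving direction and the approach direction
#'   toward the wall), zero when moving away; `t_hat` is `t_plus` for
#'   CCW-preferring agents (chirality +1) and `t_minus` for CW-preferring
#'   ones.
#'
#' @name forces
NULL

#' Agent state
#'
#' A single agent's kinematic state. The heading is the unit moving
#' direction; it equals `velocity/|velocity|` whenever the speed exceeds a
#' 1e-6 m/s floor and is persisted unchanged below it (the moving direction
#' is undefined at rest).
#'
#' @param position Length-2 position, m.
#' @param velocity Length-2 velocity, m/s.
#' @param heading Optional unit heading; derived from velocity if omitted
#'   and the speed is above the floor.
#' @param chirality +1 (prefers CCW), -1 (prefers CW) or NA (no turning
#'   preference).
#' @return A list of class `ped_agent`.
#' @export
agent_state <- function(position, velocity, heading = NULL, chirality = NA) {
  stopifnot(length(position) == 2L, length(velocity) == 2L)
  sp <- sqrt(sum(velocity^2))
  if (is.null(heading)) {
    if (sp <= SPEED_FLOOR) stop("heading required when speed is below the floor")
    heading <- velocity / sp
  }
  if (abs(sqrt(sum(heading^2)) - 1) > 1e-9) stop("heading must be a unit vector")
  structure(list(position = as.numeric(position),
                 velocity = as.numeric(velocity),
                 heading = as.numeric(heading),
                 chirality = chirality),
            class = "ped_agent")
}

SPEED_FLOOR <- 1e-6

#' @describeIn forces Self-propulsion force on one agent.
#' @param state An [agent_state()].
#' @param params A [model_params()] object.
#' @export
propulsion_force <- function(state, params) {
  sp <- sqrt(sum(state$velocity^2))
  params$mu * (params$v_d - sp) * state$heading
}

#' @describeIn forces Repulsion exerted on agent i at `r_i` by agent j at
#'   `r_j`; the force on j is the exact negation.
#' @param r_i,r_j Length-2 positions of the two agents, m.
#' @export
pair_repulsion <- function(r_i, r_j, params) {
  d <- as.numeric(r_i) - as.numeric(r_j)
  r_ij <- sqrt(sum(d^2))
  if (r_ij == 0) stop("coincident agent centres: repulsion direction undefined")
  n_hat <- d / r_ij
  two_r0 <- 2 * params$r0
  mag <- if (r_ij > two_r0) {
    params$A_p * exp(-(r_ij - two_r0) / params$B_p)
  } else {
    params$eps * (1 - r_ij / two_r0)^1.5
  }
  mag * n_hat
}

#' @describeIn forces Wall repulsion (with damping) summed over the walls in
#'   scope per `params$wall_mode`.
#' @param frames Wall frames from [wall_frames()].
#' @export
wall_force <- function(state, frames, params) {
  f <- c(0, 0)
  for (fr in frames_in_scope(frames, params)) {
    if (fr$r_iw > params$r0) {
      mag <- params$A_w1 * exp(-(fr$r_iw - params$r0) / params$B_w)
      if (fr$r_iw - params$r0 <= params$damping_range) {
        v_n <- sum(state$velocity * fr$n_hat)
        mag <- mag - params$gamma * v_n
      }
      f <- f + mag * fr$n_hat
    } else {
      f <- f + params$eps * (1 - fr$r_iw / params$r0)^1.5 * fr$n_hat
    }
  }
  f
}

#' @describeIn forces Tangential turning-preference force summed over the
#'   walls in scope. Errors if the agent carries no chirality label.
#' @export
turning_force <- function(state, frames, params) {
  if (is.na(state$chirality) || !state$chirality %in% c(-1, 1)) {
    stop("turning_force requires chirality +1 or -1")
  }
  f <- c(0, 0)
  for (fr in frames_in_scope(frames, params)) {
    # cos(alpha) against the approach direction toward the wall (-n_hat);
    # positive only while moving toward the wall
    cos_a <- -sum(state$heading * fr$n_hat)
    if (cos_a > 0) {
      t_hat <- if (state$chirality > 0) fr$t_plus else fr$t_minus
      f <- f + params$A_w2 * exp(-(fr$r_iw - params$r0) / params$B_w) * cos_a * t_hat
    }
  }
  f
}

frames_in_scope <- function(frames, params) {
  if (params$wall_mode == "nearest_only") frames[1] else frames
}

#' Total force on one agent
#'
#' Sum of propulsion, agent-agent repulsion over all other agents, wall
#' repulsion and (when enabled) the turning force, evaluated from the full
#' system state. This is the right-hand side of `m r'' = F`.
#'
#' @param i Agent index (1-based).
#' @param positions,velocities N x 2 state matrices.
#' @param headings N x 2 matrix of unit moving directions.
#' @param chiralities Integer vector (+1/-1/NA).
#' @param arena An [arena()].
#' @param params A [model_params()].
#' @return Length-2 force vector.
#' @export
total_force <- function(i, positions, velocities, headings, chiralities,
                        arena, params) {
  positions <- as_xy_matrix(positions)
  velocities <- as_xy_matrix(velocities)
  headings <- as_xy_matrix(headings)
  st <- agent_state(positions[i, ], velocities[i, ], headings[i, ],
                    if (is.null(chiralities)) NA else chiralities[i])
  f <- propulsion_force(st, params)
  n <- nrow(positions)
  if (n > 1) {
    for (j in seq_len(n)[-i]) {
      f <- f + pair_repulsion(positions[i, ], positions[j, ], params)
    }
  }
  frames <- wall_frames(positions[i, ], arena)
  f <- f + wall_force(st, frames, params)
  if (params$tp_enabled && !is.na(st$chirality)) {
    f <- f + turning_force(st, frames, params)
  }
  f
}

# All-agent force matrix via the pure-R path (reference for the compiled core).
forces_r <- function(positions, velocities, headings, chiralities, arena, params) {
  n <- nrow(as_xy_matrix(positions))
  t(vapply(seq_len(n), function(i) {
    total_force(i, positions, velocities, headings, chiralities, arena, params)
  }, numeric(2)))
}
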