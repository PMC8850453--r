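#' Turn-event eligibility criteria
#'
#' A wall-approach turn is counted only when it is unconstrained: close to
#' the faced wall, far from the corners (where motion is conditioned by the
#' confinement), with an empty field of view, and nearly perpendicular
#' incidence. Defaults follow the reference protocol: events within 2 m of
#' the faced wall, more than 2 m from every corner, a clear circular sector
#' of 2 m radius and +-70 degree aperture about the velocity, incidence
#' angle |alpha| <= 10 degrees, and a 2 s labelling window.
#'
#' @param wall_distance_max Maximum distance to the faced wall, m.
#' @param corner_exclusion Minimum distance to every corner, m.
#' @param fov_radius Field-of-view radius, m.
#' @param fov_half_angle Field-of-view half aperture, degrees (< 90).
#' @param alpha_max Maximum |incidence angle|, degrees.
#' @param label_window Trajectory window used to label the turn, s.
#' @return A list of class `turn_criteria`.
#' @export
turn_criteria <- function(wall_distance_max = 2.0, corner_exclusion = 2.0,
                          fov_radius = 2.0, fov_half_angle = 70,
                          alpha_max = 10, label_window = 2.0) {
  stopifnot(wall_distance_max > 0, corner_exclusion > 0, fov_radius > 0,
            fov_half_angle > 0, fov_half_angle < 90,
            alpha_max > 0, label_window > 0)
  structure(list(wall_distance_max = wall_distance_max,
                 corner_exclusion = corner_exclusion,
                 fov_radius = fov_radius, fov_half_angle = fov_half_angle,
                 alpha_max = alpha_max, label_window = label_window),
            class = "turn_criteria")
}

#' Detect eligible wall-approach turn events
#'
#' Scans each agent's track for frames where all four eligibility
#' conditions hold (see [turn_criteria()]); an event is anchored at the
#' first such frame and labelled CCW or CW from the signed heading change
#' over the following `label_window` seconds ([label_turn()]). After an
#' event the same agent opens no new event until it has retreated beyond
#' `wall_distance_max + 0.5` m from that wall, so one physical approach
#' yields one event. Events whose net heading change is below 1e-3 rad are
#' discarded as "no turn", as are events whose label window runs past the
#' end of the track.
#'
#' The faced wall is the one whose inward normal is most anti-parallel to
#' the velocity; alpha is the signed angle between the velocity and the
#' approach direction toward that wall (positive when the velocity points
#' to the right of the perpendicular approach). At |alpha| <= 10 degrees
#' the faced wall is unambiguous.
#'
#' @param traj Trajectory table with velocity columns (use
#'   [sliding_velocities()] first for position-only tracking data).
#' @param arena An [arena()].
#' @param criteria A [turn_criteria()].
#' @return A data.table of events: `agent_id`, `t_event`, `wall_id`,
#'   `alpha_deg`, `heading_change_rad`, `label` ("CCW"/"CW").
#' @export
detect_turn_events <- function(traj, arena = pedvortex::arena(),
                               criteria = turn_criteria()) {
  if (!all(c("vx", "vy") %in% names(traj))) {
    stop("trajectory lacks velocity columns; run sliding_velocities() first")
  }
  dt <- data.table::as.data.table(traj)
  times <- sort(unique(dt$t))
  normals <- wall_normals()
  hw <- arena$width / 2; hh <- arena$height / 2
  corners <- rbind(c(hw, hh), c(-hw, hh), c(-hw, -hh), c(hw, -hh))
  cos_fov <- cos(criteria$fov_half_angle * pi / 180)

  events <- list()
  # per-agent de-duplication state: wall we are blocked on, or NA
  ids <- sort(unique(dt$agent_id))
  blocked_wall <- stats::setNames(rep(NA_character_, length(ids)), as.character(ids))

  frames <- split(dt, by = "t", sorted = TRUE)
  for (fi in seq_along(times)) {
    fr <- frames[[fi]]
    fr <- fr[order(fr$agent_id)]
    px <- fr$x; py <- fr$y; vx <- fr$vx; vy <- fr$vy
    sp <- sqrt(vx^2 + vy^2)
    for (k in seq_along(px)) {
      id <- as.character(fr$agent_id[k])
      if (sp[k] <= SPEED_FLOOR) next
      vhat <- c(vx[k], vy[k]) / sp[k]
      d <- wall_distances(px[k], py[k], arena)
      # faced wall: inward normal most anti-parallel to the velocity
      dots <- as.vector(normals %*% vhat)
      w <- which.min(dots)
      wall <- rownames(normals)[w]
      # release the de-dup block once the agent has left the wall zone
      if (!is.na(blocked_wall[id])) {
        if (d[blocked_wall[id]] > criteria$wall_distance_max + 0.5) {
          blocked_wall[id] <- NA_character_
        } else next
      }
      if (d[wall] > criteria$wall_distance_max) next
      if (any(sqrt((corners[, 1] - px[k])^2 + (corners[, 2] - py[k])^2) <=
                criteria$corner_exclusion)) next
      # signed incidence angle vs the approach direction toward the wall
      w_hat <- -normals[w, ]
      cross_z <- w_hat[1] * vhat[2] - w_hat[2] * vhat[1]
      alpha <- -atan2(cross_z, sum(w_hat * vhat)) * 180 / pi
      if (abs(alpha) > criteria$alpha_max) next
      # field of view empty of other agents
      others <- setdiff(seq_along(px), k)
      if (length(others)) {
        ox <- px[others] - px[k]; oy <- py[others] - py[k]
        od <- sqrt(ox^2 + oy^2)
        in_fov <- od <= criteria$fov_radius &
          (ox * vhat[1] + oy * vhat[2]) >= od * cos_fov
        if (any(in_fov)) next
      }
      lab <- label_turn(dt[dt$agent_id == fr$agent_id[k]],
                        t_event = times[fi],
                        label_window = criteria$label_window)
      blocked_wall[id] <- wall
      if (is.na(lab$label)) next   # window truncated or no net turn
      events[[length(events) + 1L]] <- data.table::data.table(
        agent_id = fr$agent_id[k], t_event = times[fi], wall_id = wall,
        alpha_deg = alpha, heading_change_rad = lab$heading_change,
        label = lab$label)
    }
  }
  if (!length(events)) {
    return(data.table::data.table(agent_id = integer(), t_event = numeric(),
                                  wall_id = character(), alpha_deg = numeric(),
                                  heading_change_rad = numeric(),
                                  label = character()))
  }
  data.table::rbindlist(events)
}

#' Label one turn as CCW or CW
#'
#' Integrates the signed heading change over the labelling window starting
#' at the event anchor: the sum of atan2-based angle increments between
#' consecutive velocity directions. A positive total is a left turn (CCW in
#' the arena convention), negative is CW.
#'
#' @param track One agent's rows of a trajectory table (with velocities).
#' @param t_event Anchor time, s.
#' @param label_window Window length, s.
#' @param min_turn Net heading changes below this (rad) are reported as no
#'   turn (`label = NA`).
#' @return List with `label` ("CCW", "CW" or NA) and `heading_change` (rad;
#'   NA if the window is not fully covered by the track).
#' @export
label_turn <- function(track, t_event, label_window = 2.0, min_turn = 1e-3) {
  tr <- track[track$t >= t_event - 1e-9 &
                track$t <= t_event + label_window + 1e-9]
  tr <- tr[order(tr$t)]
  if (nrow(tr) < 2L || max(tr$t) < t_event + label_window - 1e-9) {
    return(list(label = NA_character_, heading_change = NA_real_))
  }
  ang <- atan2(tr$vy, tr$vx)
  inc <- diff(ang)
  # wrap increments to (-pi, pi]
  inc <- inc - 2 * pi * round(inc / (2 * pi))
  total <- sum(inc)
  if (abs(total) < min_turn) {
    return(list(label = NA_character_, heading_change = total))
  }
  list(label = if (total > 0) "CCW" else "CW", heading_change = total)
}

#' Summarize turning-preference counts
#'
#' Counts and fractions of CCW and CW labels with an exact binomial
#' confidence interval for the CCW fraction. Percentages are reported to
#' 0.1 percent.
#'
#' @param events Event table from [detect_turn_events()], or a character
#'   vector of "CCW"/"CW" labels.
#' @param conf_level Confidence level for the binomial interval.
#' @return List with `n`, `n_ccw`, `n_cw`, `pct_ccw`, `pct_cw` (percent,
#'   rounded to 0.1; NA when there are no events), `ccw_fraction` and
#'   `ccw_ci` (exact binomial interval).
#' @examples
#' s <- turning_preference_summary(rep(c("CCW", "CW"), c(43, 32)))
#' s$pct_ccw  # 57.3
#' @export
turning_preference_summary <- function(events, conf_level = 0.95) {
  labels <- if (is.character(events)) events else events$label
  stopifnot(all(labels %in% c("CCW", "CW")))
  n <- length(labels)
  n_ccw <- sum(labels == "CCW")
  n_cw <- n - n_ccw
  if (n == 0L) {
    return(list(n = 0L, n_ccw = 0L, n_cw = 0L,
                pct_ccw = NA_real_, pct_cw = NA_real_,
                ccw_fraction = NA_real_, ccw_ci = c(NA_real_, NA_real_)))
  }
  ci <- as.numeric(stats::binom.test(n_ccw, n, conf.level = conf_level)$conf.int)
  list(n = n, n_ccw = n_ccw, n_cw = n_cw,
       pct_ccw = round(100 * n_ccw / n, 1),
       pct_cw = round(100 * n_cw / n, 1),
       ccw_fraction = n_ccw / n, ccw_ci = ci)
}

#' Expected population left-turn fraction
#'
#' Mixture expectation for a population of right- and left-handers:
#' `f_right * p_left_given_right + (1 - f_right) * p_left_given_left`.
#' With 85 percent right-handers who turn left 72 percent of the time and
#' mirror-symmetric left-handers (28 percent left turns), this gives 65
#' percent to the nearest percent.
#'
#' @param f_right Fraction of right-handers in the population.
#' @param p_left_given_right Left-turn probability of a right-hander.
#' @param p_left_given_left Left-turn probability of a left-hander.
#' @return Expected left-turn fraction in `[0, 1]`.
#' @examples
#' expected_left_turn_fraction(0.85, 0.72, 0.28)  # 0.654
#' @export
expected_left_turn_fraction <- function(f_right, p_left_given_right,
                                        p_left_given_left) {
  args <- c(f_right, p_left_given_right, p_left_given_left)
  if (any(args < 0 | args > 1)) stop("all arguments must lie in [0, 1]")
  f_right * p_left_given_right + (1 - f_right) * p_left_given_left
}
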