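test_that("a clean lone wall approach yields exactly one labelled event", {
  for (spec in list(list(alpha = 0, turn = "CCW"),
                    list(alpha = -5, turn = "CCW"),
                    list(alpha = 8, turn = "CW"))) {
    tr <- make_fixture("wall_approach", alpha_deg = spec$alpha,
                       turn = spec$turn)
    ev <- detect_turn_events(tr)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$wall_id, "N")
    expect_equal(ev$alpha_deg, spec$alpha, tolerance = 0.5)
    expect_equal(ev$label, spec$turn)
    expect_equal(sign(ev$heading_change_rad), if (spec$turn == "CCW") 1 else -1)
  }
})

test_that("detection is reflection-dual: labels swap, alpha negates, walls mirror", {
  for (alpha in c(-6, 0, 6)) {
    pair <- make_mirror_pair("wall_approach", alpha_deg = alpha, turn = "CCW")
    e1 <- detect_turn_events(pair$original)
    e2 <- detect_turn_events(pair$mirrored)
    expect_equal(nrow(e2), nrow(e1))
    expect_equal(e2$t_event, e1$t_event)
    expect_equal(e2$label, "CW")
    expect_equal(e2$alpha_deg, -e1$alpha_deg, tolerance = 1e-9)
    expect_equal(e2$wall_id, "S")
    expect_equal(e2$heading_change_rad, -e1$heading_change_rad,
                 tolerance = 1e-12)
  }
})

test_that("detection is translation-covariant along the wall", {
  tr <- make_fixture("wall_approach", alpha_deg = -4)
  shifted <- data.table::copy(tr)
  shifted[, x := x + 1.3]
  shifted <- pedvortex:::new_trajectory(shifted, arena = attr(tr, "arena"))
  e1 <- detect_turn_events(tr)
  e2 <- detect_turn_events(shifted)
  expect_equal(e2$t_event, e1$t_event)
  expect_equal(e2$label, e1$label)
  expect_equal(e2$alpha_deg, e1$alpha_deg, tolerance = 1e-9)
})

test_that("another agent in the field of view suppresses the event", {
  tr <- make_fixture("wall_approach", alpha_deg = 0)
  # static blocker 1 m ahead on the approach line, inside the 2 m / 70 deg sector
  blocker <- data.table::data.table(t = unique(tr$t), agent_id = 2L,
                                    x = -0.5, y = 2.4, vx = 0, vy = 0,
                                    chirality = NA_integer_)
  comb <- pedvortex:::new_trajectory(rbind(tr, blocker))
  expect_equal(nrow(detect_turn_events(comb)), 0)

  # the same second agent far behind the walker does not interfere
  behind <- data.table::copy(blocker)[, y := -3]
  comb2 <- pedvortex:::new_trajectory(rbind(tr, behind))
  expect_equal(nrow(detect_turn_events(comb2)), 1)
})

test_that("approaches that stay within 2 m of a corner are excluded", {
  # straight approach to the north wall at x = 5.0: every frame with wall
  # distance <= 2 m is also within 2 m of the NE corner
  tt <- seq(0, 2.5, by = 0.04)
  tab <- data.table::data.table(t = tt, agent_id = 1L, x = 5.0, y = 1.5 + tt,
                                vx = 0, vy = 1, chirality = NA_integer_)
  tab <- tab[tab$y < 3.3]
  expect_equal(nrow(detect_turn_events(pedvortex:::new_trajectory(tab))), 0)

  # the same track 2 m farther from the corner produces an event
  tab2 <- data.table::copy(tab)[, x := 3.0]
  tab2[, y := y - 1.3]  # restart the approach outside the 2 m wall zone
  tab2 <- rbind(tab2, data.table::data.table(
    t = max(tab2$t) + seq(0.04, 2.2, by = 0.04), agent_id = 1L, x = 3.0,
    y = max(tab2$y), vx = 1, vy = 0, chirality = NA_integer_))
  ev <- detect_turn_events(pedvortex:::new_trajectory(tab2))
  expect_equal(nrow(ev), 1)
})

test_that("label_turn integrates signed heading increments over the window", {
  # 30 degree right wiggle then 120 degrees left, net +90 -> CCW
  tt <- seq(0, 2, by = 0.04)
  ang <- ifelse(tt <= 0.5, -tt / 0.5 * (30 * pi / 180),
                -30 * pi / 180 + (tt - 0.5) / 1.5 * (120 * pi / 180))
  track <- data.table::data.table(t = tt, agent_id = 1L, x = 0, y = 0,
                                  vx = cos(ang), vy = sin(ang))
  lab <- label_turn(track, t_event = 0, label_window = 2)
  expect_equal(lab$label, "CCW")
  expect_equal(lab$heading_change, 90 * pi / 180, tolerance = 1e-9)

  # straight track: no net turn
  straight <- data.table::data.table(t = tt, agent_id = 1L, x = tt, y = 0,
                                     vx = 1, vy = 0)
  expect_true(is.na(label_turn(straight, 0, 2)$label))

  # window extending past the track end is not labelled
  expect_true(is.na(label_turn(track[tt <= 1], 0, 2)$label))
})

test_that("turning_preference_summary reproduces the printed worked example", {
  s <- turning_preference_summary(rep(c("CCW", "CW"), c(43, 32)))
  expect_equal(s$n, 75)
  expect_equal(s$pct_ccw, 57.3)
  expect_equal(s$pct_cw, 42.7)
  expect_true(s$ccw_ci[1] < 43 / 75 && 43 / 75 < s$ccw_ci[2])

  empty <- turning_preference_summary(character(0))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$pct_ccw))
})

test_that("expected_left_turn_fraction is the two-component mixture", {
  expect_equal(expected_left_turn_fraction(0.85, 0.72, 0.28), 0.654)
  expect_equal(round(100 * expected_left_turn_fraction(0.85, 0.72, 0.28)), 65)
  expect_equal(expected_left_turn_fraction(1, 0.72, 0.11), 0.72)
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(expected_left_turn_fraction(0.5, p, 1 - p), 0.5)
  }
  expect_error(expected_left_turn_fraction(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("detected CCW fraction exceeds 1/2 on simulated 60/40 TP crowds", {
  pt <- model_params(gamma = 1.5, tp_enabled = TRUE)
  ev <- data.table::rbindlist(lapply(1:2, function(s) {
    tr <- run_sim(sim_config(8, duration = 200, burn_in = 0, seed = s), pt)
    detect_turn_events(tr)
  }))
  expect_gt(nrow(ev), 50)   # sparse crowds produce plenty of eligible turns
  s <- turning_preference_summary(ev)
  expect_gt(s$ccw_fraction, 0.5)
})
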