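p0 <- model_params()
near <- function(r_iw, x = 0) wall_frames(c(5.7 - r_iw, x), arena())

test_that("propulsion relaxes the speed toward v_d along the heading", {
  st <- agent_state(c(0, 0), 1.5 * c(1, 0))
  expect_equal(propulsion_force(st, p0), c(0, 0))

  st <- agent_state(c(0, 0), c(0, 0), heading = c(1, 0))
  expect_equal(propulsion_force(st, p0), c(6, 0))   # mu * v_d = 4 * 1.5

  st <- agent_state(c(0, 0), 3 * c(0.6, 0.8))      # |v| = 2 v_d: braking
  f <- propulsion_force(st, p0)
  expect_lt(sum(f * st$heading), 0)
  expect_equal(f[1] * st$heading[2], f[2] * st$heading[1])  # collinear
})

test_that("pair repulsion follows the printed piecewise law", {
  # long-range branch just outside contact: magnitude A_p
  f <- pair_repulsion(c(0.5 + 1e-12, 0), c(0, 0), p0)
  expect_equal(f[1], 13, tolerance = 1e-9)
  expect_equal(f[2], 0)

  # one decay length farther out: A_p / e
  f <- pair_repulsion(c(0.5 + 0.85, 0), c(0, 0), p0)
  expect_equal(f[1], 13 * exp(-1), tolerance = 1e-12)

  # Hertzian branch at 50% overlap: eps * (1/2)^(3/2)
  f <- pair_repulsion(c(0.25, 0), c(0, 0), p0)
  expect_equal(f[1], 200 * 0.5^1.5, tolerance = 1e-12)

  expect_error(pair_repulsion(c(1, 1), c(1, 1), p0), "coincident")
})

test_that("the contact discontinuity is as printed (A_p jump at r_ij = 2 r0)", {
  outside <- pair_repulsion(c(0.5 + 1e-9, 0), c(0, 0), p0)[1]
  at_contact <- pair_repulsion(c(0.5, 0), c(0, 0), p0)[1]
  expect_equal(outside, 13, tolerance = 1e-6)
  expect_equal(at_contact, 0)   # Hertz branch includes the contact point
})

test_that("pair forces are antisymmetric under i-j exchange", {
  set.seed(11)
  for (k in 1:25) {
    r_i <- runif(2, -3, 3)
    r_j <- r_i + runif(2, -1.5, 1.5)
    if (all(r_i == r_j)) next
    expect_equal(pair_repulsion(r_i, r_j, p0),
                 -pair_repulsion(r_j, r_i, p0))
  }
})

test_that("wall force matches the printed law at the wall surface", {
  pn <- model_params(wall_mode = "nearest_only")
  st <- agent_state(c(0, 0), c(0, 0), heading = c(1, 0))
  # at r_iw = r0 (limit from outside): A_w1 along the inward normal
  f <- wall_force(st, near(0.25 + 1e-12), pn)
  expect_equal(f, c(-15, 0), tolerance = 1e-9)

  # inside the wall contact: Hertzian
  f <- wall_force(st, near(0.15), pn)
  expect_equal(f, c(-200 * (1 - 0.15 / 0.25)^1.5, 0), tolerance = 1e-12)

  # gamma damping: approaching at v_n = -1 adds +gamma to the repulsion
  pg <- model_params(gamma = 1.5, wall_mode = "nearest_only")
  st <- agent_state(c(0, 0), c(1, 0))  # moving toward the east wall
  f <- wall_force(st, near(0.25 + 1e-12), pg)
  expect_equal(f, c(-16.5, 0), tolerance = 1e-9)

  # the damping term only acts within damping_range of the wall surface
  pg_far <- model_params(gamma = 2, wall_mode = "nearest_only")
  pg_zero <- model_params(gamma = 0, wall_mode = "nearest_only")
  f_far <- wall_force(st, near(0.25 + 1.5), pg_far)   # 1.5 m > damping_range
  expect_equal(f_far, wall_force(st, near(0.25 + 1.5), pg_zero))
  f_in <- wall_force(st, near(0.25 + 0.5), pg_far)
  expect_false(isTRUE(all.equal(f_in, wall_force(st, near(0.25 + 0.5), pg_zero))))
})

test_that("wall repulsion is exponentially negligible far from all walls", {
  big <- arena(40, 40)
  st <- agent_state(c(0, 0), c(0, 0), heading = c(1, 0))
  f <- wall_force(st, wall_frames(c(0, 0), big), model_params())
  expect_lt(sqrt(sum(f^2)), 1e-6)
})

test_that("turning force is tangential, chirality-signed and gated on approach", {
  pt <- model_params(tp_enabled = TRUE, wall_mode = "nearest_only")
  fr <- near(0.25 + 1e-12)

  # walking parallel to the east wall: alpha = 90 degrees -> zero
  st <- agent_state(c(0, 0), c(0, 1), chirality = 1L)
  expect_equal(turning_force(st, fr, pt), c(0, 0))

  # head-on (alpha = 0) at the surface: magnitude A_w2 along t_plus
  st <- agent_state(c(0, 0), c(1, 0), chirality = 1L)
  expect_equal(turning_force(st, fr, pt), c(0, 9), tolerance = 1e-9)
  # CW-preferring agent pushed along t_minus
  st_cw <- agent_state(c(0, 0), c(1, 0), chirality = -1L)
  expect_equal(turning_force(st_cw, fr, pt), c(0, -9), tolerance = 1e-9)

  # moving away from the wall (alpha = 135 degrees): zero
  st <- agent_state(c(0, 0), sqrt(0.5) * c(-1, 1), chirality = 1L)
  expect_equal(turning_force(st, fr, pt), c(0, 0))

  expect_error(turning_force(agent_state(c(0, 0), c(1, 0)), fr, pt),
               "chirality")
})

test_that("turning force magnitude decreases monotonically in |alpha|", {
  pt <- model_params(tp_enabled = TRUE, wall_mode = "nearest_only")
  fr <- near(0.7)
  alphas <- seq(0, 90, by = 5) * pi / 180
  mags <- vapply(alphas, function(a) {
    st <- agent_state(c(0, 0), c(cos(a), sin(a)), chirality = 1L)
    sqrt(sum(turning_force(st, fr, pt)^2))
  }, numeric(1))
  expect_true(all(diff(mags) <= 1e-12))
  expect_equal(max(mags), mags[1])
})

test_that("total force reduces to propulsion for a lone agent at the centre", {
  st <- random_states(1, seed = 1)
  st$positions[1, ] <- c(0, 0)
  st$velocities[1, ] <- c(0, 0)
  st$headings[1, ] <- c(0, 1)
  f <- total_force(1, st$positions, st$velocities, st$headings,
                   st$chiralities, arena(), model_params(gamma = 1.7))
  expect_equal(f, c(0, 6))   # opposite wall terms cancel exactly at the centre
})

test_that("pair contributions cancel in the total-force sum (Newton's third law)", {
  st <- random_states(2, seed = 3, with_chirality = FALSE)
  p_nw <- model_params()
  f1 <- total_force(1, st$positions, st$velocities, st$headings, NULL, arena(), p_nw)
  f2 <- total_force(2, st$positions, st$velocities, st$headings, NULL, arena(), p_nw)
  g1 <- pair_repulsion(st$positions[1, ], st$positions[2, ], p_nw)
  expect_equal(f1 - g1 + (f2 + g1), f1 + f2)
  # and removing the pair term leaves single-agent forces
  solo1 <- total_force(1, st$positions[1, , drop = FALSE],
                       st$velocities[1, , drop = FALSE],
                       st$headings[1, , drop = FALSE], NULL, arena(), p_nw)
  expect_equal(f1 - g1, solo1)
})

test_that("total force is reflection-equivariant given a chirality flip", {
  pt <- model_params(gamma = 1.2, tp_enabled = TRUE)
  for (seed in 1:4) {
    st <- random_states(8, seed = seed)
    mir <- mirror_state(st$positions, st$velocities, st$chiralities)
    mir$headings <- st$headings
    mir$headings[, 2] <- -mir$headings[, 2]
    f <- pedvortex:::forces_r(st$positions, st$velocities, st$headings,
                              st$chiralities, arena(), pt)
    fm <- pedvortex:::forces_r(mir$positions, mir$velocities, mir$headings,
                               mir$chiralities, arena(), pt)
    expect_equal(fm[, 1], f[, 1], tolerance = 1e-13)
    expect_equal(fm[, 2], -f[, 2], tolerance = 1e-13)
  }
})

test_that("compiled force kernel agrees with the pure-R reference", {
  for (seed in 1:4) {
    st <- random_states(12, seed = 100 + seed)
    for (p in list(model_params(gamma = 1.5, tp_enabled = TRUE),
                   model_params(wall_mode = "nearest_only"),
                   model_params(gamma = 2, damping_range = Inf))) {
      fr <- pedvortex:::forces_r(st$positions, st$velocities, st$headings,
                                 st$chiralities, arena(), p)
      fc <- pedvortex:::.forces_cpp(st$positions, st$velocities, st$headings,
                                    st$chiralities, unclass(p), 11.4, 6.7)
      expect_equal(fc, fr, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})
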