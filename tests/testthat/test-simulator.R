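test_that("config validation enforces the protocol invariants", {
  expect_error(sim_config(0), ">= 1")
  expect_error(sim_config(5, duration = 100, burn_in = 100), "burn_in")
  expect_error(sim_config(5, dt = 0.01, record_interval = 0.015), "multiple")
  cfg <- sim_config(5, duration = 10, burn_in = 2)
  expect_s3_class(cfg, "ped_config")
})

test_that("initialization respects separation, clearance and the 60/40 split", {
  p <- model_params(tp_enabled = TRUE)
  cfg <- sim_config(24, duration = 10, burn_in = 2, seed = 42)
  st <- initialize_agents(cfg, p)

  expect_equal(sum(st$chiralities == 1L), 14)   # round(0.6 * 24)
  expect_equal(sum(st$chiralities == -1L), 10)
  expect_gte(min(dist(st$positions)), 1.0)
  wd <- pmin(5.7 - abs(st$positions[, 1]), 3.35 - abs(st$positions[, 2]))
  expect_gte(min(wd), 0.25 + 0.1)
  expect_equal(rowSums(st$headings^2), rep(1, 24))
  expect_equal(sqrt(rowSums(st$velocities^2)), rep(1.5, 24))

  # determinism and independence from the caller's RNG state
  set.seed(999)
  st2 <- initialize_agents(cfg, p)
  expect_identical(st, st2)

  st1 <- initialize_agents(sim_config(1, duration = 5, burn_in = 1), p)
  expect_equal(nrow(st1$positions), 1)

  # over-crowded request fails with a clear error
  cfg_bad <- sim_config(300, duration = 5, burn_in = 1,
                        initial_min_separation = 1.5)
  expect_error(initialize_agents(cfg_bad, p), "crowded")
})

test_that("a single step advances position with the pre-step velocity", {
  st <- list(positions = matrix(c(0, 0), 1), velocities = matrix(c(1.5, 0), 1),
             headings = matrix(c(1, 0), 1), chiralities = NA_integer_)
  out <- step_agents(st, arena(), model_params(), dt = 0.01)
  expect_equal(out$positions[1, ], c(0.015, 0))
  expect_equal(out$velocities[1, 1], 1.5, tolerance = 1e-4)
})

test_that("single-agent speed follows the closed-form relaxation, first order in dt", {
  big <- arena(40, 40)   # walls negligible: isolates the propulsion ODE
  p <- model_params()
  endpoint_err <- function(dt) {
    cfg <- sim_config(1, duration = 1, burn_in = 0.1, dt = dt,
                      record_interval = 0.1, seed = 1, initial_speed = 0)
    st <- list(positions = matrix(c(0, 0), 1), velocities = matrix(c(0, 0), 1),
               headings = matrix(c(1, 0), 1), chiralities = NA_integer_)
    traj <- run_sim(cfg, p, big, initial_state = st)
    sp <- sqrt(traj$vx^2 + traj$vy^2)
    exact <- 1.5 * (1 - exp(-4 * traj$t))
    max(abs(sp - exact))
  }
  e1 <- endpoint_err(0.01)
  e2 <- endpoint_err(0.005)
  # worst-case local truncation ~ mu^2 dt t e^(-mu t)/2 * v_d ~ 0.011 at dt = 0.01
  expect_lt(e1, 0.02)
  expect_gt(e1 / e2, 1.7)          # halving dt about halves the error
  expect_lt(e1 / e2, 2.3)
})

test_that("run_sim records the expected frames and is deterministic", {
  cfg <- sim_config(4, duration = 1, burn_in = 0.2, seed = 7)
  p <- model_params(gamma = 0.5)
  traj <- run_sim(cfg, p)
  expect_equal(length(unique(traj$t)), 11)    # 100 steps, every 10th + t = 0
  expect_equal(nrow(traj), 44)
  expect_true(all(abs(traj$x) < 5.7 & abs(traj$y) < 3.35))

  traj2 <- run_sim(cfg, p)
  expect_identical(as.data.frame(traj), as.data.frame(traj2))
})

test_that("pure-R and compiled engines integrate identically", {
  cfg <- sim_config(5, duration = 0.5, burn_in = 0.1, seed = 9)
  p <- model_params(gamma = 1.5, tp_enabled = TRUE)
  tc <- run_sim(cfg, p, engine = "cpp")
  tr <- run_sim(cfg, p, engine = "r")
  expect_equal(as.data.frame(tr), as.data.frame(tc), tolerance = 1e-10)
})

test_that("mirrored runs are exact frame-by-frame mirrors (L negated)", {
  p <- model_params(gamma = 1.5, tp_enabled = TRUE)
  cfg <- sim_config(12, duration = 30, burn_in = 5, seed = 21)
  st <- initialize_agents(cfg, p)
  mir <- mirror_state(st$positions, st$velocities, st$chiralities)
  mir$headings <- st$headings
  mir$headings[, 2] <- -mir$headings[, 2]
  t1 <- run_sim(cfg, p, initial_state = st)
  t2 <- run_sim(cfg, p, initial_state = mir)
  expect_identical(t2$x, t1$x)
  expect_identical(t2$y, -t1$y)
  expect_identical(l_series(t2)$L, -l_series(t1)$L)
})

test_that("containment holds over a long default-parameter run", {
  p <- model_params(gamma = 1.5)
  traj <- run_sim(sim_config(24, duration = 60, burn_in = 10, seed = 4), p)
  expect_true(all(abs(traj$x) < 5.7 & abs(traj$y) < 3.35))

  # undamped crowd: recorded speeds stay within the 2 v_d sanity bound
  traj0 <- run_sim(sim_config(24, duration = 60, burn_in = 10, seed = 4),
                   model_params(gamma = 0))
  sp <- sqrt(traj0$vx^2 + traj0$vy^2)
  expect_true(all(sp >= 0 & sp <= 2 * 1.5))
})

test_that("an escaping agent raises an informative error", {
  st <- list(positions = matrix(c(5.5, 0), 1), velocities = matrix(c(1.5, 0), 1),
             headings = matrix(c(1, 0), 1), chiralities = NA_integer_)
  cfg <- sim_config(1, duration = 2, burn_in = 0.5, dt = 0.2,
                    record_interval = 0.2)
  expect_error(run_sim(cfg, model_params(), initial_state = st),
               "agent 1 left the arena")
})

test_that("max_pairwise_overlap measures the worst recorded frame", {
  tab <- data.table::data.table(
    t = c(0, 0, 1, 1), agent_id = c(1L, 2L, 1L, 2L),
    x = c(0, 1, 0, 0.4), y = 0, vx = 0, vy = 0, chirality = NA_integer_)
  traj <- pedvortex:::new_trajectory(tab)
  expect_equal(max_pairwise_overlap(traj, r0 = 0.25), (0.5 - 0.4) / 0.5)
  expect_equal(max_pairwise_overlap(pedvortex:::new_trajectory(tab[t == 0]),
                                    r0 = 0.25), 0)
})
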