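test_that("wrap_angle maps any finite angle into (-pi, pi] and preserves it mod 2*pi", {
  expect_equal(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_error(wrap_angle(Inf), "finite")
  thetas <- seq(-25, 25, length.out = 2001)
  w <- wrap_angle(thetas)
  expect_true(all(w > -pi & w <= pi))
  expect_true(all(abs((w - thetas) %% (2 * pi)) %% (2 * pi) < 1e-9))
})

test_that("attraction matches hand evaluation and is odd and distance-decaying", {
  p <- global_dynamics_params(k_g = 2, c1 = 0, c2 = 0)
  expect_equal(attraction(1.3, goal_context(1.3, 4), p), 0)
  expect_equal(attraction(0.2, goal_context(0, 5), p), -0.4)
  # |A| strictly decreases with goal distance when c1 > 0, c2 = 0
  p2 <- global_dynamics_params(k_g = 2, c1 = 0.7, c2 = 0)
  a <- vapply(seq(0, 20, by = 0.5),
              function(d) abs(attraction(0.4, goal_context(0, d), p2)),
              numeric(1))
  expect_true(all(diff(a) < 0))
  # odd function of the wrapped angular error at fixed distance
  p3 <- global_dynamics_params()
  for (delta in seq(-3.1, 3.1, by = 0.3)) {
    expect_equal(attraction(delta, goal_context(0, 2), p3),
                 -attraction(-delta, goal_context(0, 2), p3))
  }
})

test_that("repulsion matches hand evaluation, is odd, decays in distance and vanishes at pi for steep c3", {
  p <- global_dynamics_params(k_o = 1, c3 = 1, c4 = 0)
  expect_equal(repulsion(0.4, obstacle_context(), p), 0)
  expect_equal(repulsion(0.7, obstacle_context(0.7, 3), p), 0)
  expect_equal(repulsion(0.5, obstacle_context(0, 9), p), 0.5 * exp(-0.5),
               tolerance = 1e-12)
  # odd in the angular error
  for (delta in seq(-3, 3, by = 0.4)) {
    expect_equal(repulsion(delta, obstacle_context(0, 1), p),
                 -repulsion(-delta, obstacle_context(0, 1), p))
  }
  # strict decay in obstacle distance when c4 > 0
  p4 <- global_dynamics_params(k_o = 1, c3 = 1, c4 = 0.8)
  r <- vapply(seq(0, 10, by = 0.5),
              function(d) repulsion(0.5, obstacle_context(0, d), p4),
              numeric(1))
  expect_true(all(diff(r) < 0))
  # steep angular decay kills repulsion near +/- pi
  p5 <- global_dynamics_params(k_o = 1, c3 = 40, c4 = 0)
  expect_lt(abs(repulsion(3.1, obstacle_context(0, 1), p5)), 1e-10)
  # contributions sum over obstacles
  expect_equal(repulsion(0.5, obstacle_context(c(0, 0), c(9, 9)), p),
               2 * repulsion(0.5, obstacle_context(0, 9), p))
})

test_that("heading acceleration combines damping, attraction and repulsion", {
  p <- global_dynamics_params(b = 1)
  eq <- agent_state(0, 0, phi = 0.8, phi_dot = 0)
  expect_equal(heading_acceleration(eq, goal_context(0.8, 3),
                                    obstacle_context(), p), 0)
  # pure damping: b = 1, phi_dot = 0.3, goal error zero
  st <- agent_state(0, 0, phi = 0.8, phi_dot = 0.3)
  expect_equal(heading_acceleration(st, goal_context(0.8, 3),
                                    obstacle_context(), p), -0.3)
  # restoring: sign opposes the wrapped goal error
  for (err in seq(-3.1, 3.1, by = 0.2)) {
    if (abs(err) < 1e-12) next
    st <- agent_state(0, 0, phi = err, phi_dot = 0)
    acc <- heading_acceleration(st, goal_context(0, 3),
                                obstacle_context(), p)
    expect_true(sign(acc) == -sign(err))
  }
})

test_that("speed drive reproduces sigmoid midpoint, constant baseline and retreat limit", {
  chasing1 <- agent_speed_params(k = 0, c5 = 1, c6 = 10, c7 = 7)
  expect_equal(speed_drive(7, chasing1), 0.5)
  expect_equal(speed_drive(3, agent_speed_params(c9 = 0.5)), 0.5)
  avoiding1 <- agent_speed_params(k = 0, c5 = 1, c6 = 1, c7 = 5, c8 = 3)
  expect_equal(speed_drive(60, avoiding1), 1 - 3, tolerance = 1e-6)
  expect_error(speed_drive(-1, chasing1), ">= 0")
})

test_that("a fully equilibrated state is a fixed point of the integrator", {
  p <- global_dynamics_params()
  sp <- agent_speed_params()  # F identically zero
  st <- agent_state(1, 2, phi = 0.4, phi_dot = 0, s = 0)
  nxt <- step_agent(st, goal_context(0.4, 5), obstacle_context(),
                    p, sp, dt = 0.01)
  expect_equal(unlist(nxt), unlist(st))
  expect_error(step_agent(st, goal_context(0.4, 5), obstacle_context(),
                          p, sp, dt = 0), "dt")
})

test_that("noise-free speed relaxes to F(d) within 1% after seven time constants", {
  p <- global_dynamics_params(tau = 0.5)
  sp <- agent_speed_params(c5 = 1, c6 = 10, c7 = 2, c9 = 0.3)
  d_fix <- 6
  target <- speed_drive(d_fix, sp)
  st <- agent_state(0, 0, phi = 0, phi_dot = 0, s = 0)
  g <- goal_context(0, d_fix)
  s <- 0
  n <- round(7 * p$tau / 0.01)
  for (i in seq_len(n)) {
    st <- step_agent(st, g, obstacle_context(), p, sp, 0.01)
    st$x <- 0; st$y <- 0  # hold the goal distance fixed
  }
  expect_lt(abs(st$s - target) / abs(target), 0.01)
})

test_that("the integrator converges at first order in dt", {
  p <- global_dynamics_params()
  sp <- agent_speed_params(c5 = 1, c6 = 1, c7 = 3)
  run <- function(dt) {
    st <- agent_state(0, 0, phi = 2, phi_dot = 0, s = 0)
    df <- simulate_to_goal(st, c(50, 0), p, sp, dt, duration = 5)
    unlist(df[nrow(df), ])
  }
  ref <- run(0.0005)
  err <- function(dt) max(abs(run(dt) - ref))
  e1 <- err(0.05)
  e2 <- err(0.025)
  expect_lt(e2, e1)               # refining dt reduces the error
  expect_gt(e1 / e2, 1.5)         # at roughly first order
  expect_lt(e1 / e2, 3)
})

test_that("heading asymptotically locks onto a stationary goal from any initial heading", {
  p <- global_dynamics_params()
  sp <- agent_speed_params()  # zero drive: agent spins in place
  for (phi0 in seq(-3, 3, by = 0.75)) {
    df <- simulate_to_goal(agent_state(0, 0, phi = phi0), c(4, 0),
                           p, sp, dt = 0.01, duration = 15)
    expect_lt(abs(wrap_angle(df$phi[nrow(df)] - 0)), 1e-3)
  }
})

test_that("obstacles deflect the heading but never touch the speed dynamics", {
  p <- global_dynamics_params(k_o = 5)
  sp <- agent_speed_params(c5 = 1, c6 = 1, c7 = 2, k_eps = 0)
  st <- agent_state(0, 0, phi = 0.5, phi_dot = 0.1, s = 0.4)
  g <- goal_context(0, 3)
  obs <- obstacle_context(c(0.6, -0.2), c(1, 2))
  with_obs <- step_agent(st, g, obs, p, sp, 0.01)
  without <- step_agent(st, g, obstacle_context(), p, sp, 0.01)
  expect_identical(with_obs$s, without$s)
  expect_false(isTRUE(all.equal(with_obs$phi_dot, without$phi_dot)))
})

test_that("deterministic stepping is bit-reproducible and noisy stepping is seed-reproducible", {
  p <- global_dynamics_params()
  sp <- agent_speed_params(c5 = 1, c6 = 2, c7 = 1, k_eps = 0.3)
  st <- agent_state(0.3, -0.2, phi = 1, phi_dot = 0.05, s = 0.2)
  g <- goal_context(0.4, 2)
  a <- step_agent(st, g, obstacle_context(), p, sp, 0.01, noise_draw = 0)
  b <- step_agent(st, g, obstacle_context(), p, sp, 0.01, noise_draw = 0)
  expect_identical(unlist(a), unlist(b))
  set.seed(11); n1 <- rnorm(1)
  set.seed(11); n2 <- rnorm(1)
  expect_identical(
    unlist(step_agent(st, g, obstacle_context(), p, sp, 0.01, n1)),
    unlist(step_agent(st, g, obstacle_context(), p, sp, 0.01, n2)))
})
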