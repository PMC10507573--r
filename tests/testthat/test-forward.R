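test_that("probability mass is conserved to 1e-10 at every timestep", {
  for (v in variants) {
    traj <- cached_trajectory(v)
    total <- traj$active + traj$cum_dead_predation +
      traj$cum_dead_starvation + traj$cum_no_payoff
    expect_true(all(abs(total - 1) < 1e-10))
  }
})

test_that("the cohort starts as a point mass doing a single activity", {
  m1 <- cached_trajectory("model1")
  expect_equal(m1$mass[101, 1, 1], 1)  # all mass at (x = 100, a = 0)
  expect_equal(sum(m1$mass[, , 1]), 1)
  # antipredator-practice juveniles all play at birth ...
  expect_equal(unname(m1$activity[1, "play"]), 1)
  # ... while reproductive-ability juveniles with foraging practice all forage
  m3b <- cached_trajectory("model3b")
  expect_equal(unname(m3b$activity[1, "forage"]), 1)
})

test_that("activity time-course rows sum to one and absorption never reverses", {
  for (v in c("model1", "model3b")) {
    traj <- cached_trajectory(v)
    tc <- activity_timecourse(traj)
    expect_true(all(abs(rowSums(tc[, -1]) - 1) < 1e-10))
    expect_true(all(diff(tc$p_no_payoff_cum) >= -1e-14))
    expect_true(all(as.matrix(tc[, -1]) >= 0))
  }
})

test_that("play collapses at weaning when its benefit runs through foraging success", {
  tc <- activity_timecourse(cached_trajectory("model2"))
  expect_gt(mean(tc$p_play[tc$t < 30]), 0.2)
  expect_lt(max(tc$p_play[tc$t >= 60]), 0.01)
})

test_that("rest is negligible when both reserves and ability feed the final payoff", {
  traj <- cached_trajectory("model3a")
  tc <- activity_timecourse(traj)
  expect_lt(unname(lifetime_budget(traj)["rest"]), 0.02)
  expect_lt(max(tc$p_rest), 0.1)
})

test_that("lifetime budget normalises activity over acting mass", {
  traj <- cached_trajectory("model1")
  b <- lifetime_budget(traj)
  expect_equal(sum(b), 1, tolerance = 1e-10)
  expect_equal(unname(b["play"]),
               sum(traj$activity[, "play"]) / sum(traj$activity))
  # the default parameterisation itself predicts substantial play from the
  # sensitivity-analysis start state
  b50 <- lifetime_budget(cached_trajectory("model1", x_start = 50))
  expect_gte(unname(b50["play"]), 0.05)
})

test_that("play share is zero when play is dominated outright", {
  cfg <- tiny_config("model1", m_f0 = 0.0002, m_fA = 0.0002, m_p = 0.0002,
                     c_p = 2)
  traj <- forward_propagate(solve_policy(cfg), 15, 0)
  expect_equal(unname(lifetime_budget(traj)["play"]), 0)
})

test_that("state densities marginalise the active mass", {
  traj <- cached_trajectory("model1")
  for (axis in c("energy", "ability")) {
    d <- state_density(traj, axis)
    sums <- as.numeric(tapply(d$mass, d$t, sum))
    expect_equal(sums, traj$active, tolerance = 1e-12)
    expect_true(all(d$ge10pct == (d$mass >= 0.1)))
  }
  d0 <- state_density(traj, "energy")
  expect_equal(d0$mass[d0$t == 0 & d0$level == 100], 1)
  # most surviving individuals end at maximum ability
  da <- state_density(traj, "ability")
  top_late <- da$mass[da$t == 180 & da$level == traj$config$A]
  expect_gt(top_late / traj$active[181], 0.5)
})

test_that("degenerate and invalid starts are handled explicitly", {
  sol <- solve_policy(tiny_config())
  expect_error(forward_propagate(sol, 0, 0), "x_start")
  expect_error(forward_propagate(sol, 25, 0), "x_start")
  # a start inside the no-payoff region is absorbed immediately: with no
  # energy income and a terminal bar at the ceiling, no state has value
  cfg <- play_config("model1", X = 20, A = 2, T = 10, tau = 5,
                     x_crit = 20, y_e = 0, w_z = 0)
  traj <- forward_propagate(solve_policy(cfg), 15, 0)
  expect_equal(traj$cum_no_payoff[1], 1)
  expect_warning(b <- lifetime_budget(traj), "degenerate")
  expect_true(attr(b, "degenerate"))
})
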