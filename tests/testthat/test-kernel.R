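test_that("foraging outcome tree multiplies survival, yield, and practice odds", {
  # constant y_z = 0.7 and m_f = 0.002 (ability acts on the terminal payoff
  # in this variant), after weaning, so no provisioning branch
  cfg <- play_config("model3b")
  tr <- transition_distribution(100, 0, 60, "forage", cfg)
  expect_equal(tr$death_probability, 0.002)
  b <- tr$branches
  hit <- b[b$x_next == 103 & b$a_next == 1, ]
  expect_equal(hit$prob, (1 - 0.002) * 0.7 * 0.8)  # 0.55888
  expect_equal(sum(b$prob) + tr$death_probability, 1, tolerance = 1e-14)
})

test_that("rest is a single deterministic branch with minimal hazard", {
  cfg <- play_config("model1")
  tr <- transition_distribution(100, 5, 60, "rest", cfg)
  expect_equal(nrow(tr$branches), 1L)
  expect_equal(tr$branches$x_next, 99L)
  expect_equal(tr$branches$a_next, 5L)
  expect_equal(tr$branches$prob, 1 - 0.0001)
  expect_equal(tr$death_probability, 0.0001)
})

test_that("branches that cannot keep reserves above zero are starvation", {
  cfg <- play_config("model1")
  # play at x = 3 costs 3 with no gains after weaning: certain starvation
  tr <- transition_distribution(3, 0, 60, "play", cfg)
  expect_equal(nrow(tr$branches), 0L)
  expect_equal(tr$death_probability, 1)
  # during provisioning, the successful provisioning branch rescues
  tr2 <- transition_distribution(3, 0, 10, "play", cfg)
  expect_true(all(tr2$branches$x_next == 3L))
  expect_equal(tr$death_probability + sum(tr$branches$prob), 1)
})

test_that("kernel probabilities always sum to one with bounded next states", {
  for (v in variants) {
    cfg <- play_config(v)
    set.seed(99)
    for (i in 1:40) {
      x <- sample(cfg$X, 1)
      a <- sample(0:cfg$A, 1)
      t <- sample(0:(cfg$T - 1), 1)
      for (action in c("forage", "play", "rest")) {
        tr <- transition_distribution(x, a, t, action, cfg)
        expect_equal(sum(tr$branches$prob) + tr$death_probability, 1,
                     tolerance = 1e-12)
        expect_true(all(tr$branches$prob >= 0))
        expect_true(tr$death_probability >= 0)
        if (nrow(tr$branches)) {
          expect_true(all(tr$branches$x_next >= 1 &
                            tr$branches$x_next <= cfg$X))
          expect_true(all(tr$branches$a_next >= a &
                            tr$branches$a_next <= min(a + 1, cfg$A)))
        }
      }
    }
  }
})

test_that("ability endpoints reach the coupled rates exactly", {
  m1 <- play_config("model1")
  tr <- transition_distribution(200, m1$A, 60, "forage", m1)
  expect_identical(tr$death_probability, m1$m_p)  # m_f(A) = m_p
  m2 <- play_config("model2")
  tr2 <- transition_distribution(200, m2$A, 60, "forage", m2)
  gain <- tr2$branches[tr2$branches$x_next == 203, ]
  expect_equal(sum(gain$prob), (1 - m2$m_f0) * 0.9)  # y_z(A) = 0.9
})

test_that("a never-successful provisioner is the same as a weaned kernel", {
  cfg <- play_config("model1", w_z = 0)
  for (x in c(5, 100, 300)) {
    for (action in c("forage", "play", "rest")) {
      pre <- transition_distribution(x, 2, 10, action, cfg)   # t < tau
      post <- transition_distribution(x, 2, 100, action, cfg) # t >= tau
      expect_equal(pre$branches, post$branches)
      expect_equal(pre$death_probability, post$death_probability)
    }
  }
})

test_that("richer reserves stochastically dominate: survival tail never drops", {
  cfg <- play_config("model2")
  set.seed(7)
  for (i in 1:20) {
    x <- sample(cfg$X - 1, 1)
    a <- sample(0:cfg$A, 1)
    t <- sample(0:(cfg$T - 1), 1)
    action <- sample(c("forage", "play", "rest"), 1)
    lo <- transition_distribution(x, a, t, action, cfg)
    hi <- transition_distribution(x + 1, a, t, action, cfg)
    tail_mass <- function(tr, k) sum(tr$branches$prob[tr$branches$x_next >= k])
    for (k in 1:cfg$X) {
      expect_gte(tail_mass(hi, k) - tail_mass(lo, k), -1e-14)
    }
  }
})

test_that("the vectorized expectation agrees with per-state enumeration", {
  cfg <- tiny_config("model2")
  kt <- playsdp:::.kernel_tables(cfg)
  Vnext <- matrix(runif((cfg$X + 1) * (cfg$A + 1)), cfg$X + 1)
  Vnext[1, ] <- 0
  for (action in c("forage", "play", "rest")) {
    for (provisioning in c(TRUE, FALSE)) {
      EV <- playsdp:::.bellman_action(Vnext, kt[[action]], provisioning,
                                      cfg$X, cfg$A)
      t_probe <- if (provisioning) 0L else cfg$tau
      for (x in c(1, 2, 10, 20)) {
        for (a in 0:cfg$A) {
          expect_equal(EV[x + 1, a + 1],
                       action_value(x, a, t_probe, action, Vnext, cfg),
                       tolerance = 1e-13)
        }
      }
    }
  }
})
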