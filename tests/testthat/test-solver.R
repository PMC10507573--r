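test_that("the horizon slice is the terminal reward and values stay in [0, 1]", {
  sol <- cached_solution("model3a")
  cfg <- sol$config
  expect_equal(sol$value[, , cfg$T + 1],
               playsdp:::.terminal_matrix(cfg) *
                 matrix(c(0, rep(1, cfg$X)), cfg$X + 1, cfg$A + 1))
  expect_true(all(sol$value >= 0 & sol$value <= 1))
  expect_true(all(sol$value[1, , ] == 0))  # starvation level worth nothing
})

test_that("value is monotone in reserves and in ability on miniature grids", {
  for (v in variants) {
    sol <- solve_policy(tiny_config(v))
    expect_true(all(apply(sol$value, c(2, 3), diff) >= -1e-12))
    expect_true(all(apply(sol$value, c(1, 3), diff) >= -1e-12))
  }
})

test_that("optimal value attains the chosen action's value and dominates the rest", {
  sol <- cached_solution("model1")
  cfg <- sol$config
  set.seed(13)
  for (i in 1:60) {
    x <- sample(cfg$X, 1)
    a <- sample(0:cfg$A, 1)
    t <- sample(0:(cfg$T - 1), 1)
    Vnext <- sol$value[, , t + 2]
    av <- vapply(c("forage", "play", "rest"), function(act) {
      action_value(x, a, t, act, Vnext, cfg)
    }, numeric(1))
    ustar <- sol$value[x + 1, a + 1, t + 1]
    expect_equal(ustar, max(av), tolerance = 1e-12)
    code <- sol$policy[x + 1, a + 1, t + 1]
    if (code > 0) {
      expect_equal(ustar, av[[c("forage", "play", "rest")[code]]],
                   tolerance = 1e-12)
    } else {
      expect_equal(ustar, 0)
    }
  }
})

test_that("zero-value states and only they are assigned no behaviour", {
  sol <- cached_solution("model1")
  TT <- sol$config$T
  live <- sol$value[-1, , 1:TT]
  pol <- sol$policy[-1, , ]
  expect_true(all((pol == 0L) == (live == 0)))
})

test_that("backward induction matches exhaustive recursion on a miniature grid", {
  for (v in c("model1", "model3a")) {
    cfg <- tiny_config(v)
    sol <- solve_policy(cfg)
    for (st in list(c(15, 0), c(8, 2))) {
      expect_equal(sol$value[st[1] + 1, st[2] + 1, 1],
                   recursive_value_oracle(st[1], st[2], 0, cfg),
                   tolerance = 1e-10)
    }
  }
})

test_that("resting to the finish line lower-bounds the value when affordable", {
  for (v in c("model1", "model2")) {
    sol <- cached_solution(v)
    cfg <- sol$config
    for (t in c(0, 50, 120, 199)) {
      x <- 0:cfg$X
      feasible <- x - cfg$c_r * (cfg$T - t) >= cfg$x_crit
      if (!any(feasible)) next
      bound <- (1 - cfg$m_r)^(cfg$T - t)
      expect_true(all(sol$value[feasible, , t + 1] >= bound - 1e-12))
    }
  }
})

test_that("policy slices are exhaustive and omit dominated play", {
  sol <- solve_policy(tiny_config("model1"))
  sl <- policy_slice(sol, 0)
  expect_identical(nrow(sl), sol$config$T * sol$config$X)
  expect_setequal(names(sl), c("t", "x", "choice"))

  # same risk and cost as foraging but worse practice: play cannot win
  cfg <- tiny_config("model1", m_f0 = 0.0002, m_fA = 0.0002, m_p = 0.0002,
                     c_p = 1)
  dom <- solve_policy(cfg)
  sl_top <- policy_slice(dom, cfg$A)
  expect_false("play" %in% sl_top$choice)
})
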