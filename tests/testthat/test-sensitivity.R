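test_that("a singleton sweep reproduces a direct solve-and-propagate", {
  cfg <- tiny_config("model1")
  sw <- oat_sweep(cfg, "m_p", grid = cfg$m_p, x_start = 15, a_start = 0)
  direct <- lifetime_budget(forward_propagate(solve_policy(cfg), 15, 0))
  expect_equal(sw$shares$share_play, unname(direct["play"]), tolerance = 1e-12)
  expect_equal(sw$shares$share_forage, unname(direct["forage"]),
               tolerance = 1e-12)
  expect_equal(nrow(sw$shares), 1L)
})

test_that("per-value shares are a full budget and qualify against the threshold", {
  cfg <- tiny_config("model2")
  sw <- oat_sweep(cfg, "s_p", grid = c(0, 0.5, 1), x_start = 15,
                  threshold = 0.05)
  sums <- rowSums(sw$shares[, c("share_forage", "share_play", "share_rest")])
  expect_true(all(abs(sums - 1) < 1e-10 | is.na(sums)))
  expect_identical(sw$shares$qualifies,
                   !is.na(sw$shares$share_play) & sw$shares$share_play >= 0.05)
  expect_error(oat_sweep(cfg, "s_p", grid = c(0.5, 0.1)), "increasing")
  expect_error(oat_sweep(cfg, "bogus", grid = 1), "unknown")
})

test_that("qualifying ranges are maximal runs, including split ranges", {
  fake <- structure(
    list(parameter = "s_f", grid = seq(0, 0.8, by = 0.1),
         shares = data.frame(value = seq(0, 0.8, by = 0.1),
                             share_play = c(0.2, 0.1, 0.06, 0.01, 0.02,
                                            0.08, 0.2, 0.3, 0.4)),
         threshold = 0.05),
    class = "play_sweep"
  )
  iv <- qualifying_range(fake)
  expect_length(iv, 2L)
  expect_equal(iv[[1]], c(0, 0.2))
  expect_equal(iv[[2]], c(0.5, 0.8))

  fake$shares$share_play[] <- 0.5
  expect_equal(qualifying_range(fake), list(c(0, 0.8)))
  fake$shares$share_play[] <- 0
  expect_equal(qualifying_range(fake), list())
})

test_that("default grids span the conventional sweep ranges", {
  g <- default_sweep_grid("s_p")
  expect_length(g, 21L)
  expect_equal(range(g), c(0, 1))
  gi <- default_sweep_grid("c_p")
  expect_true(all(gi == round(gi)))
  expect_equal(range(gi), c(1, 14))
  expect_error(default_sweep_grid("variant"), "no default sweep span")
})

test_that("the default play-risk value sits inside its own qualifying range", {
  # the baseline m_p = 0.0002 must itself predict >= 5% lifetime play; a play
  # risk above foraging risk must not (sweep on the full default grid)
  cfg <- play_config("model1")
  sw <- oat_sweep(cfg, "m_p", grid = c(0.0002, 0.02), x_start = 50,
                  a_start = 0)
  expect_true(sw$shares$qualifies[1])
  expect_false(sw$shares$qualifies[2])
  expect_equal(sw$qualifying, list(c(0.0002, 0.0002)))
})
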