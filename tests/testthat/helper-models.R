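# Shared fixtures: full-size solves are expensive (~2 s each), so default
# solutions and trajectories are computed once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached_solution <- function(variant) {
  if (is.null(.fixture_cache[[variant]])) {
    .fixture_cache[[variant]] <- solve_policy(play_config(variant))
  }
  .fixture_cache[[variant]]
}

cached_trajectory <- function(variant, x_start = 100, a_start = 0) {
  key <- paste(variant, x_start, a_start, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      forward_propagate(cached_solution(variant), x_start, a_start)
  }
  .fixture_cache[[key]]
}

# miniature grid: exhaustive checks stay cheap
tiny_config <- function(variant = "model1", ...) {
  play_config(variant, X = 20, A = 3, T = 10, tau = 5, w_e = 2, y_e = 3,
              c_f = 1, c_p = 2, x_crit = 10, ...)
}

variants <- c("model1", "model2", "model3a", "model3b")
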