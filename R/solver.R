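#' Solve the model by exact backward induction
#'
#' Computes the optimal value function \code{U*(x, a, t)} — the probability-
#' weighted terminal payoff achieved under optimal behaviour from state
#' \code{(x, a)} at time \code{t} — and the optimal choice function
#' \code{Psi(x, a, t)} over the full integer state grid. The terminal slice
#' equals \code{\link{terminal_reward}}; each earlier slice is the pointwise
#' maximum over the three activities of the expected next value under the
#' one-step kernel.
#'
#' The choice is the strict argmax, with exact ties breaking toward
#' foraging, then play, then rest. The tie handling is visible in the
#' results: when ability pays off only at the horizon (models 3a/3b), the
#' timing of play within a life is almost value-neutral and broad regions
#' of the state space agree to near machine precision, so the optimal
#' activity there is decided by sub-\code{1e-12} value differences. A
#' positive \code{tie_tol} instead treats all activities within that band
#' of the maximum as tied and picks the preferred one, which yields
#' cleaner policy maps but collapses the near-indifferent mixture of
#' foraging and play that characterises the reproductive-ability variants.
#' States with optimal value exactly zero — from which the terminal criterion is unreachable —
#' get the choice \code{"none"}: no behaviour is optimal there and the
#' forward model absorbs such individuals into the no-payoff class.
#'
#' @param config a \code{\link{play_config}}.
#' @param tie_tol nonnegative band within which action values count as tied
#'   (default 0: strict argmax).
#' @return An object of class \code{play_solution}: a list with
#' \describe{
#'   \item{\code{value}}{numeric array \code{(X+1) x (A+1) x (T+1)}, indexed
#'     by \code{x = 0..X}, \code{a = 0..A}, \code{t = 0..T}; the starvation
#'     level \code{x = 0} is fixed at 0.}
#'   \item{\code{policy}}{integer array \code{(X+1) x (A+1) x T} over decision
#'     epochs \code{t = 0..T-1}, coded 0 = none, 1 = forage, 2 = play,
#'     3 = rest (see \code{\link{action_levels}}).}
#'   \item{\code{config}}{the configuration solved.}
#' }
#' @examples
#' cfg <- play_config("model1", X = 40, A = 5, T = 20, tau = 5, x_crit = 20)
#' sol <- solve_policy(cfg)
#' dim(sol$value)
#' @export
solve_policy <- function(config, tie_tol = 0) {
  stopifnot(inherits(config, "play_config"), tie_tol >= 0)
  X <- config$X; A <- config$A; TT <- config$T
  kt <- .kernel_tables(config)

  value <- array(0, dim = c(X + 1L, A + 1L, TT + 1L))
  policy <- array(0L, dim = c(X + 1L, A + 1L, TT))
  value[, , TT + 1L] <- .terminal_matrix(config)
  value[1L, , TT + 1L] <- 0  # x = 0 is the starvation-absorbed level

  tol <- tie_tol
  for (t in (TT - 1L):0L) {
    Vnext <- value[, , t + 2L]
    provisioning <- t < config$tau
    EVf <- .bellman_action(Vnext, kt$forage, provisioning, X, A)
    EVp <- .bellman_action(Vnext, kt$play, provisioning, X, A)
    EVr <- .bellman_action(Vnext, kt$rest, provisioning, X, A)
    best <- pmax(EVf, EVp, EVr)
    choice <- matrix(3L, X + 1L, A + 1L)
    choice[EVp >= best - tol] <- 2L
    choice[EVf >= best - tol] <- 1L
    choice[best <= 0] <- 0L
    choice[1L, ] <- 0L
    best[1L, ] <- 0
    value[, , t + 1L] <- best
    policy[, , t + 1L] <- choice
  }

  structure(list(value = value, policy = policy, config = config),
            class = "play_solution")
}

#' Activity codes used in policy arrays
#'
#' @return character vector naming integer codes 0..3:
#'   \code{c(none = 0, forage = 1, play = 2, rest = 3)}.
#' @export
action_levels <- function() {
  c(none = 0L, forage = 1L, play = 2L, rest = 3L)
}

# integer policy codes -> factor labels
.decode_action <- function(code) {
  factor(c("none", "forage", "play", "rest")[code + 1L],
         levels = c("forage", "play", "rest", "none"))
}

#' @export
print.play_solution <- function(x, ...) {
  cfg <- x$config
  cat("Solved play-as-practice model (", cfg$variant, ")\n", sep = "")
  cat(sprintf("  grid: (x, a, t) = %d x %d x %d states\n",
              cfg$X + 1L, cfg$A + 1L, cfg$T))
  tab <- table(.decode_action(as.vector(x$policy)))
  cat("  policy composition:",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate the policy at a fixed ability level
#'
#' Serialises one ability slice of the choice function as an exhaustive
#' \code{(t, x)} table — the data behind a policy map panel (time on one
#' axis, reserves on the other) at a given ability.
#'
#' @param solution a \code{\link{solve_policy}} result.
#' @param fixed_a ability level in \code{0..A}.
#' @return data frame with columns \code{t} (0..T-1), \code{x} (1..X) and
#'   \code{choice} (factor forage/play/rest/none); \code{T * X} rows.
#' @export
policy_slice <- function(solution, fixed_a) {
  stopifnot(inherits(solution, "play_solution"))
  cfg <- solution$config
  if (fixed_a < 0 || fixed_a > cfg$A) stop("fixed_a out of range 0..A")
  grid <- expand.grid(x = seq_len(cfg$X), t = 0:(cfg$T - 1L))
  code <- as.vector(solution$policy[-1L, fixed_a + 1L, ])
  data.frame(t = grid$t, x = grid$x, choice = .decode_action(code))
}

#' Exhaustive recursive value oracle for miniature instances
#'
#' Independently recomputes \code{U*(x, a, t)} by plain depth-first recursion
#' over the outcome tree of \code{\link{transition_distribution}}, maximising
#' over activities at each step, with per-state memoisation. No vectorised
#' grid arithmetic is involved, so this serves as a cross-check of
#' \code{\link{solve_policy}} on small grids (it is far too slow for the
#' default grid).
#'
#' @param x,a,t state at which to evaluate.
#' @param config a \code{\link{play_config}} (keep \code{X*A*T} small).
#' @return the optimal value at \code{(x, a, t)}.
#' @export
recursive_value_oracle <- function(x, a, t, config) {
  stopifnot(inherits(config, "play_config"))
  memo <- new.env(parent = emptyenv())
  eval_state <- function(x, a, t) {
    if (x <= 0) return(0)
    if (t == config$T) return(terminal_reward(x, a, config))
    key <- paste(x, a, t)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- 0
    for (action in c("forage", "play", "rest")) {
      tr <- transition_distribution(x, a, t, action, config)
      v <- 0
      br <- tr$branches
      for (i in seq_len(nrow(br))) {
        v <- v + br$prob[i] * eval_state(br$x_next[i], br$a_next[i], t + 1L)
      }
      if (v > best) best <- v
    }
    memo[[key]] <- best
    best
  }
  eval_state(x, a, t)
}
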