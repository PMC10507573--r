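#' One-step stochastic transition kernel
#'
#' Enumerates the full outcome tree for one live state and one activity:
#' predation (probability depending on the activity and, in model 1, on
#' ability), a stochastic foraging yield (\code{+y_e} with probability
#' \code{y_z(a)}, foraging only), parental provisioning (\code{+w_e} with
#' probability \code{w_z}, any activity, only while \code{t < tau}), and a
#' stochastic ability increment (\code{+1}, capped at \code{A}, with
#' probability \code{s_f} / \code{s_p}; rest never trains). The energy update
#' is \code{x' = min(x - c_action + gains, X)}; any branch landing at
#' \code{x' <= 0} is starvation and is folded into the death probability
#' together with predation.
#'
#' @param x,a,t live state: \code{1 <= x <= X}, \code{0 <= a <= A},
#'   \code{0 <= t < T}.
#' @param action \code{"forage"}, \code{"play"} or \code{"rest"}.
#' @param config a \code{\link{play_config}}.
#' @return A list of class \code{play_transition} with \code{branches}
#'   (data frame \code{x_next}, \code{a_next}, \code{prob} for the surviving,
#'   non-starving branches, zero-probability branches dropped) and
#'   \code{death_probability}. Branch probabilities and
#'   \code{death_probability} sum to 1.
#' @examples
#' cfg <- play_config("model3b")
#' tr <- transition_distribution(100, 5, 60, "rest", cfg)
#' tr$branches           # single branch at x' = 99
#' tr$death_probability  # m_r
#' @export
transition_distribution <- function(x, a, t, action, config) {
  stopifnot(inherits(config, "play_config"))
  action <- match.arg(action, c("forage", "play", "rest"))
  if (length(x) != 1L || length(a) != 1L || length(t) != 1L) {
    stop("transition_distribution is defined for a single state")
  }
  if (x < 1 || x > config$X) {
    stop("x must be a live reserve level in 1..X")
  }
  if (a < 0 || a > config$A) stop("a out of range 0..A")
  if (t < 0 || t >= config$T) {
    stop("t must be a decision epoch in 0..T-1")
  }

  m <- .mortality(config, action, a)
  cost <- switch(action, forage = config$c_f, play = config$c_p,
                 rest = config$c_r)
  s <- switch(action, forage = config$s_f, play = config$s_p, rest = 0)
  yz <- if (action == "forage") .forage_success(config, a) else 0
  provisioning <- t < config$tau

  gains <- c(0, config$y_e)
  p_gain <- c(1 - yz, yz)
  prov <- if (provisioning) c(0, config$w_e) else 0
  p_prov <- if (provisioning) c(1 - config$w_z, config$w_z) else 1
  dskill <- c(0L, 1L)
  p_skill <- c(1 - s, s)

  xn <- an <- integer(0)
  pr <- numeric(0)
  death <- m
  for (i in seq_along(gains)) {
    for (j in seq_along(prov)) {
      for (k in seq_along(dskill)) {
        p <- (1 - m) * p_gain[i] * p_prov[j] * p_skill[k]
        if (p == 0) next
        xp <- min(x - cost + gains[i] + prov[j], config$X)
        if (xp <= 0) {
          death <- death + p
        } else {
          xn <- c(xn, as.integer(xp))
          an <- c(an, min(a + dskill[k], config$A))
          pr <- c(pr, p)
        }
      }
    }
  }
  structure(
    list(
      branches = data.frame(x_next = xn, a_next = an, prob = pr),
      death_probability = death
    ),
    class = "play_transition"
  )
}

# --- vectorized kernel machinery shared by the solver and the forward model --

# Branch table for one action: list of branches, each with a scalar energy
# gain, a skill indicator, and a probability vector over a = 0..A (survival
# factor excluded). Depends on t only through whether provisioning is active.
.branch_table <- function(config, action, provisioning) {
  A <- config$A
  s <- switch(action, forage = config$s_f, play = config$s_p, rest = 0)
  if (action == "forage") {
    yz <- .forage_success(config, 0:A)
    yields <- list(list(g = 0L, p = 1 - yz), list(g = config$y_e, p = yz))
  } else {
    yields <- list(list(g = 0L, p = rep(1, A + 1L)))
  }
  provs <- if (provisioning) {
    list(list(g = 0L, p = 1 - config$w_z), list(g = config$w_e, p = config$w_z))
  } else {
    list(list(g = 0L, p = 1))
  }
  skills <- list(list(d = 0L, p = 1 - s), list(d = 1L, p = s))

  out <- list()
  for (y in yields) {
    for (w in provs) {
      for (sk in skills) {
        p <- y$p * w$p * sk$p
        if (all(p == 0)) next
        out[[length(out) + 1L]] <-
          list(gain = y$g + w$g, dskill = sk$d, p = p)
      }
    }
  }
  out
}

# Precompute, per action, the cost, survival vector over a, and the branch
# tables for the provisioning-on and provisioning-off phases.
.kernel_tables <- function(config) {
  lapply(stats::setNames(nm = c("forage", "play", "rest")), function(action) {
    list(
      cost = switch(action, forage = config$c_f, play = config$c_p,
                    rest = config$c_r),
      surv = 1 - .mortality(config, action, 0:config$A),
      branches = list(
        on = .branch_table(config, action, provisioning = TRUE),
        off = .branch_table(config, action, provisioning = FALSE)
      )
    )
  })
}

# Shift a (X+1) x (A+1) matrix one ability column to the right, folding the
# top column onto itself (a' = min(a + 1, A)). Used when scattering mass.
.shift_ability <- function(mat) {
  A1 <- ncol(mat)
  out <- matrix(0, nrow(mat), A1)
  out[, 2:A1] <- mat[, 1:(A1 - 1L), drop = FALSE]
  out[, A1] <- out[, A1] + mat[, A1]
  out
}

# Expected next value of one action: (X+1) x (A+1) matrix of
# (1 - m(a)) * sum_branches p_branch(a) * Vnext[x', a'] (death contributes 0).
# Gather formulation: for each branch the row map x -> x' is an index lookup.
.bellman_action <- function(Vnext, kt, provisioning, X, A) {
  phase <- if (provisioning) "on" else "off"
  x <- seq_len(X)
  EV <- matrix(0, X + 1L, A + 1L)
  cols_stay <- seq_len(A + 1L)
  cols_up <- pmin(cols_stay + 1L, A + 1L)
  for (b in kt$branches[[phase]]) {
    xp <- pmin(x - kt$cost + b$gain, X)
    ok <- xp >= 1L
    if (!any(ok)) next
    cols <- if (b$dskill == 1L) cols_up else cols_stay
    contrib <- matrix(0, X + 1L, A + 1L)
    contrib[1L + x[ok], ] <- Vnext[1L + xp[ok], cols, drop = FALSE]
    EV <- EV + contrib * rep(b$p, each = X + 1L)
  }
  EV * rep(kt$surv, each = X + 1L)
}

#' Expected value of an activity against next-period values
#'
#' The one-step Bellman operand: the expectation of the \code{t + 1} value
#' slice over the transition kernel of the given activity, with death
#' (predation or starvation) contributing zero. Computed by direct
#' enumeration through \code{\link{transition_distribution}}; the solver uses
#' an equivalent vectorized form.
#'
#' @param x,a,t live state (see \code{\link{transition_distribution}}).
#' @param action \code{"forage"}, \code{"play"} or \code{"rest"}.
#' @param next_values \code{(X+1) x (A+1)} matrix of values at \code{t + 1},
#'   rows indexed by \code{x = 0..X}, columns by \code{a = 0..A}.
#' @param config a \code{\link{play_config}}.
#' @return scalar expected value.
#' @export
action_value <- function(x, a, t, action, next_values, config) {
  tr <- transition_distribution(x, a, t, action, config)
  if (nrow(tr$branches) == 0L) return(0)
  sum(tr$branches$prob *
        next_values[cbind(tr$branches$x_next + 1L, tr$branches$a_next + 1L)])
}
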