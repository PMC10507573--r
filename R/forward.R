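#' Deterministic forward propagation of a cohort under the optimal policy
#'
#' Pushes a unit probability mass, starting as a point at
#' \code{(x_start, a_start)} at \code{t = 0}, through the one-step kernel of
#' the activity the policy prescribes in each state. At every decision epoch,
#' mass sitting in zero-value states (choice \code{"none"}) is first absorbed
#' into the no-payoff class — no behaviour is optimal there and no terminal
#' payoff is achievable; the remaining mass acts, with predation and
#' starvation branch mass accumulating in their respective death classes.
#'
#' @param solution a \code{\link{solve_policy}} result.
#' @param x_start,a_start initial state (live: \code{1 <= x_start <= X}).
#' @return An object of class \code{cohort_trajectory}: a list with
#' \describe{
#'   \item{\code{mass}}{array \code{(X+1) x (A+1) x (T+1)} of active mass at
#'     each decision epoch (after no-payoff absorption at that epoch).}
#'   \item{\code{activity}}{\code{T x 3} matrix of forage/play/rest mass
#'     acting at each \code{t = 0..T-1} (fractions of the initial cohort).}
#'   \item{\code{cum_dead_predation}, \code{cum_dead_starvation},
#'     \code{cum_no_payoff}}{length \code{T+1} cumulative absorbed masses as
#'     of each epoch (after that epoch's no-payoff absorption).}
#'   \item{\code{mean_x}, \code{mean_a}}{length \code{T+1} means of the
#'     active mass.}
#'   \item{\code{active}}{length \code{T+1} total active mass.}
#'   \item{\code{terminal_payoff}}{expected terminal payoff of the cohort,
#'     which equals \code{U*(x_start, a_start, 0)}.}
#'   \item{\code{x_start}, \code{a_start}, \code{config}}{inputs.}
#' }
#' At every epoch, active mass plus the three cumulative absorbed classes
#' sums to 1 (to numerical precision).
#' @examples
#' cfg <- play_config("model1", X = 40, A = 5, T = 20, tau = 5, x_crit = 20)
#' traj <- forward_propagate(solve_policy(cfg), x_start = 15, a_start = 0)
#' lifetime_budget(traj)
#' @export
forward_propagate <- function(solution, x_start, a_start) {
  stopifnot(inherits(solution, "play_solution"))
  cfg <- solution$config
  X <- cfg$X; A <- cfg$A; TT <- cfg$T
  if (x_start < 1 || x_start > X) stop("x_start must be a live level in 1..X")
  if (a_start < 0 || a_start > A) stop("a_start out of range 0..A")
  kt <- .kernel_tables(cfg)

  mass <- array(0, dim = c(X + 1L, A + 1L, TT + 1L))
  activity <- matrix(0, TT, 3L,
                     dimnames = list(NULL, c("forage", "play", "rest")))
  cum_pred <- cum_starv <- cum_nopay <- numeric(TT + 1L)
  M <- matrix(0, X + 1L, A + 1L)
  M[x_start + 1L, a_start + 1L] <- 1
  pred <- starv <- nopay <- 0
  x <- seq_len(X)

  for (t in 0:(TT - 1L)) {
    pol <- solution$policy[, , t + 1L]
    dead_zone <- pol == 0L & M > 0
    if (any(dead_zone)) {
      nopay <- nopay + sum(M[dead_zone])
      M[dead_zone] <- 0
    }
    mass[, , t + 1L] <- M
    cum_pred[t + 1L] <- pred
    cum_starv[t + 1L] <- starv
    cum_nopay[t + 1L] <- nopay

    phase <- if (t < cfg$tau) "on" else "off"
    Mnew <- matrix(0, X + 1L, A + 1L)
    for (j in 1:3) {
      action <- c("forage", "play", "rest")[j]
      sel <- M * (pol == j)
      pa <- sum(sel)
      activity[t + 1L, j] <- pa
      if (pa == 0) next
      k <- kt[[action]]
      pred <- pred + sum(colSums(sel) * (1 - k$surv))
      surv_mass <- sel * rep(k$surv, each = X + 1L)
      for (b in k$branches[[phase]]) {
        contrib <- surv_mass * rep(b$p, each = X + 1L)
        if (b$dskill == 1L) contrib <- .shift_ability(contrib)
        raw <- x - k$cost + b$gain
        dead <- raw < 1L
        capped <- raw > X
        okl <- !dead & !capped
        if (any(dead)) starv <- starv + sum(contrib[1L + x[dead], ])
        if (any(okl)) {
          Mnew[1L + raw[okl], ] <- Mnew[1L + raw[okl], ] +
            contrib[1L + x[okl], , drop = FALSE]
        }
        if (any(capped)) {
          Mnew[X + 1L, ] <- Mnew[X + 1L, ] +
            colSums(contrib[1L + x[capped], , drop = FALSE])
        }
      }
    }
    M <- Mnew
  }
  mass[, , TT + 1L] <- M
  cum_pred[TT + 1L] <- pred
  cum_starv[TT + 1L] <- starv
  cum_nopay[TT + 1L] <- nopay

  active <- apply(mass, 3L, sum)
  mean_x <- mean_a <- rep(NA_real_, TT + 1L)
  for (tt in seq_len(TT + 1L)) {
    if (active[tt] > 0) {
      mean_x[tt] <- sum(rowSums(mass[, , tt]) * (0:X)) / active[tt]
      mean_a[tt] <- sum(colSums(mass[, , tt]) * (0:A)) / active[tt]
    }
  }
  terminal_payoff <- sum(M * .terminal_matrix(cfg))

  structure(
    list(mass = mass, activity = activity,
         cum_dead_predation = cum_pred, cum_dead_starvation = cum_starv,
         cum_no_payoff = cum_nopay, active = active,
         mean_x = mean_x, mean_a = mean_a,
         terminal_payoff = terminal_payoff,
         x_start = as.integer(x_start), a_start = as.integer(a_start),
         config = cfg),
    class = "cohort_trajectory"
  )
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat(sprintf(
    "Cohort trajectory (%s), start (x = %d, a = %d)\n",
    x$config$variant, x$x_start, x$a_start))
  b <- lifetime_budget(x)
  cat(sprintf("  lifetime budget: forage %.1f%%, play %.1f%%, rest %.1f%%\n",
              100 * b[["forage"]], 100 * b[["play"]], 100 * b[["rest"]]))
  cat(sprintf("  expected terminal payoff %.4f; final no-payoff mass %.4f\n",
              x$terminal_payoff, x$cum_no_payoff[length(x$cum_no_payoff)] +
                x$cum_dead_predation[length(x$cum_dead_predation)] +
                x$cum_dead_starvation[length(x$cum_dead_starvation)]))
  invisible(x)
}

#' Activity time-course of a propagated cohort
#'
#' Per-timestep proportions of the initial cohort choosing each activity,
#' plus the cumulative no-payoff class (dead by predation or starvation, or
#' absorbed in states from which the terminal criterion is unreachable) —
#' the stacked-proportions convention of the model's time-course figures.
#' Each row sums to 1.
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @return data frame with columns \code{t} (0..T-1), \code{p_forage},
#'   \code{p_play}, \code{p_rest}, \code{p_no_payoff_cum}.
#' @export
activity_timecourse <- function(trajectory) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  TT <- trajectory$config$T
  idx <- seq_len(TT)
  data.frame(
    t = 0:(TT - 1L),
    p_forage = trajectory$activity[, "forage"],
    p_play = trajectory$activity[, "play"],
    p_rest = trajectory$activity[, "rest"],
    p_no_payoff_cum = trajectory$cum_dead_predation[idx] +
      trajectory$cum_dead_starvation[idx] + trajectory$cum_no_payoff[idx]
  )
}

#' Lifetime activity budget
#'
#' The share of total lifetime activity devoted to each behaviour: each
#' activity's mass summed over all decision epochs, normalised by the total
#' acting (alive, payoff-capable) mass. This active-mass normalisation is
#' the convention behind the "play for at least 5\% of lifetime" sensitivity
#' criterion.
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @return named numeric vector \code{(forage, play, rest)} summing to 1,
#'   with attribute \code{degenerate = TRUE} (and all shares \code{NaN}) if
#'   the cohort was absorbed immediately and no mass ever acted.
#' @export
lifetime_budget <- function(trajectory) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  tot <- colSums(trajectory$activity)
  denom <- sum(tot)
  if (denom == 0) {
    warning("no mass ever acted: degenerate lifetime budget")
    out <- c(forage = NaN, play = NaN, rest = NaN)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- tot / denom
  attr(out, "degenerate") <- FALSE
  out
}

#' Marginal state densities over time
#'
#' Marginal distribution of the active cohort mass over energy reserves or
#' ability at each decision epoch, with a flag for cells holding at least
#' 10\% of the initial cohort (the high-density contour of the model's
#' density maps).
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @param axis \code{"energy"} (marginal over \code{x}) or \code{"ability"}
#'   (marginal over \code{a}).
#' @return data frame with columns \code{t} (0..T), \code{level},
#'   \code{mass}, \code{ge10pct}.
#' @export
state_density <- function(trajectory, axis = c("energy", "ability")) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  axis <- match.arg(axis)
  cfg <- trajectory$config
  levels <- if (axis == "energy") 0:cfg$X else 0:cfg$A
  fold <- if (axis == "energy") rowSums else colSums
  out <- lapply(0:cfg$T, function(t) {
    m <- fold(trajectory$mass[, , t + 1L])
    data.frame(t = t, level = levels, mass = m, ge10pct = m >= 0.1)
  })
  do.call(rbind, out)
}
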