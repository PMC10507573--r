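#' Model configuration for the play-as-practice decision model
#'
#' Constructs the full parameter set for one of four variants of a
#' finite-horizon state-dependent model of juvenile time allocation. An
#' individual with integer energy reserves \code{x} (0..\code{X}; \code{x = 0}
#' is death by starvation) and integer ability \code{a} (0..\code{A}) makes
#' \code{T} sequential choices among foraging, play and rest. Ability is an
#' instrumental skill whose effect defines the variant:
#' \describe{
#'   \item{\code{model1}}{ability linearly reduces predation risk while
#'     foraging, from \code{m_f0} at \code{a = 0} down to \code{m_fA}
#'     (default: the play risk \code{m_p}) at \code{a = A}.}
#'   \item{\code{model2}}{ability linearly raises foraging success probability
#'     from \code{y_z0} (default 0.1) to \code{y_zA} (default 0.9).}
#'   \item{\code{model3a}}{ability linearly raises the probability of
#'     successful reproduction at the horizon, from \code{omega_z0} (0.1) to
#'     \code{omega_zA} (0.9); foraging gives no practice (\code{s_f = 0}), so
#'     play is the only route to ability.}
#'   \item{\code{model3b}}{as \code{model3a} but foraging is better practice
#'     than play (\code{s_f = 0.8 > s_p = 0.5}).}
#' }
#'
#' Unspecified parameters take the variant's defaults. Variant-coupled
#' defaults resolve after overrides: in \code{model1}, \code{m_fA} defaults to
#' the resolved \code{m_p}. Three alias names are accepted for the constant
#' (non-ability-dependent) forms: \code{m_f} (sets \code{m_f0 = m_fA}, or only
#' \code{m_f0} in \code{model1} where the upper endpoint stays tied to
#' \code{m_p}), \code{y_z} (sets both endpoints, or only \code{y_z0} in
#' \code{model2}), and \code{omega_z} (sets \code{omega_z0}).
#'
#' @param variant one of \code{"model1"}, \code{"model2"}, \code{"model3a"},
#'   \code{"model3b"}.
#' @param ... named parameter overrides (see Details for field names).
#'
#' @return An object of class \code{play_config}: a named list with fields
#'   \code{variant}, \code{X}, \code{A}, \code{T}, \code{tau}, \code{w_e},
#'   \code{w_z}, \code{y_e}, \code{y_z0}, \code{y_zA}, \code{c_f}, \code{c_p},
#'   \code{c_r}, \code{m_f0}, \code{m_fA}, \code{m_p}, \code{m_r}, \code{s_f},
#'   \code{s_p}, \code{x_crit}, \code{q}, \code{omega_z0}, \code{omega_zA}.
#'
#' @details Field meanings (energy in integer units per timestep, risks as
#'   per-timestep probabilities):
#' \itemize{
#'   \item \code{X}, \code{A}, \code{T}: state-grid caps and horizon
#'     (defaults 300, 100, 200).
#'   \item \code{tau}: end of parental provisioning; provisioning (gain
#'     \code{w_e} with probability \code{w_z}) applies at decision epochs
#'     \code{t < tau}, regardless of activity.
#'   \item \code{y_e}, \code{y_z0}, \code{y_zA}: foraging gain and its success
#'     probability at the two ability endpoints.
#'   \item \code{c_f}, \code{c_p}, \code{c_r}: per-timestep energy costs of
#'     foraging, play, rest (\code{c_r} may be negative).
#'   \item \code{m_f0}, \code{m_fA}, \code{m_p}, \code{m_r}: predation risks.
#'   \item \code{s_f}, \code{s_p}: per-bout probabilities of a +1 ability
#'     increment from foraging / play (rest never trains).
#'   \item \code{x_crit}, \code{q}: terminal criterion; reaching
#'     \code{x >= x_crit} at \code{T} scores \code{(x/X)^q} (times the
#'     reproduction probability in models 3a/3b), else 0.
#' }
#'
#' @examples
#' cfg <- play_config("model1")
#' cfg$m_f0   # 0.005
#' cfg$m_fA   # equals cfg$m_p
#' play_config("model2", tau = 40)$y_z0
#' @export
play_config <- function(variant = c("model1", "model2", "model3a", "model3b"),
                        ...) {
  variant <- match.arg(variant)
  overrides <- list(...)
  .play_config_build(variant, overrides)
}

.config_fields <- c(
  "X", "A", "T", "tau", "w_e", "w_z", "y_e", "y_z0", "y_zA",
  "c_f", "c_p", "c_r", "m_f0", "m_fA", "m_p", "m_r", "s_f", "s_p",
  "x_crit", "q", "omega_z0", "omega_zA"
)
.config_aliases <- c("m_f", "y_z", "omega_z")
.integer_fields <- c("X", "A", "T", "tau", "w_e", "y_e",
                     "c_f", "c_p", "c_r", "x_crit")
.prob_fields <- c("w_z", "y_z0", "y_zA", "m_f0", "m_fA", "m_p", "m_r",
                  "s_f", "s_p", "omega_z0", "omega_zA")

# expand the constant-form aliases to endpoint fields for a given variant
.expand_aliases <- function(variant, overrides) {
  out <- overrides
  if (!is.null(out$m_f)) {
    if (variant == "model1") {
      out$m_f0 <- out$m_f
    } else {
      out$m_f0 <- out$m_fA <- out$m_f
    }
    out$m_f <- NULL
  }
  if (!is.null(out$y_z)) {
    if (variant == "model2") {
      out$y_z0 <- out$y_z
    } else {
      out$y_z0 <- out$y_zA <- out$y_z
    }
    out$y_z <- NULL
  }
  if (!is.null(out$omega_z)) {
    out$omega_z0 <- out$omega_z
    out$omega_z <- NULL
  }
  out
}

.play_config_build <- function(variant, overrides) {
  if (length(overrides) &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all parameter overrides must be named")
  }
  overrides <- .expand_aliases(variant, overrides)
  unknown <- setdiff(names(overrides), .config_fields)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }

  cfg <- list(
    X = 300L, A = 100L, T = 200L, tau = 50L,
    w_e = 3L, w_z = 0.7, y_e = 5L, y_z0 = 0.7, y_zA = 0.7,
    c_f = 2L, c_p = 3L, c_r = 1L,
    m_f0 = 0.002, m_fA = 0.002, m_p = 0.0002, m_r = 0.0001,
    s_f = 0.8, s_p = 0.5, x_crit = 150L, q = 0,
    omega_z0 = 0.1, omega_zA = 0.9
  )
  if (variant == "model1") {
    cfg$m_f0 <- 0.005
    cfg$m_fA <- NA_real_  # resolved to m_p below unless overridden
  } else if (variant == "model2") {
    cfg$y_z0 <- 0.1
    cfg$y_zA <- 0.9
  } else if (variant == "model3a") {
    cfg$s_f <- 0
  }

  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (variant == "model1" && is.na(cfg$m_fA)) cfg$m_fA <- cfg$m_p

  for (nm in .integer_fields) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      stop(nm, " must be a single integer value")
    }
    cfg[[nm]] <- as.integer(v)
  }
  for (nm in .prob_fields) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]")
    }
    cfg[[nm]] <- as.numeric(v)
  }
  if (!is.numeric(cfg$q) || length(cfg$q) != 1L || is.na(cfg$q) || cfg$q < 0) {
    stop("q must be a single nonnegative number")
  }
  cfg$q <- as.numeric(cfg$q)
  if (cfg$X < 1L) stop("X must be positive")
  if (cfg$A < 0L) stop("A must be nonnegative")
  if (cfg$T < 1L) stop("T must be positive")
  if (cfg$x_crit < 1L || cfg$x_crit > cfg$X) {
    stop("x_crit must satisfy 0 < x_crit <= X")
  }
  if (cfg$tau < 1L || cfg$tau > cfg$T) stop("tau must satisfy 0 < tau <= T")
  if (cfg$w_e < 0L) stop("w_e must be nonnegative")
  if (cfg$y_e < 0L) stop("y_e must be nonnegative")
  if (cfg$c_f > cfg$c_p) {
    warning("c_f > c_p: play is usually at least as costly as foraging")
  }
  if (cfg$m_r > cfg$m_p) {
    warning("m_r > m_p: rest is usually at least as safe as play")
  }

  cfg$variant <- variant
  cfg <- cfg[c("variant", .config_fields)]
  attr(cfg, "overrides") <- overrides
  class(cfg) <- "play_config"
  cfg
}

#' Re-derive a configuration with one parameter changed
#'
#' Rebuilds the configuration from the variant defaults with the given
#' parameter overridden (on top of any overrides already present), so that
#' variant-coupled defaults stay consistent: e.g. changing \code{m_p} in
#' \code{model1} also moves the coupled upper endpoint \code{m_fA} unless it
#' was itself explicitly set. Accepts the same alias names as
#' \code{\link{play_config}}. This is the update rule used by
#' \code{\link{oat_sweep}}.
#'
#' @param config a \code{play_config}.
#' @param parameter field or alias name.
#' @param value new value.
#' @return a new \code{play_config}.
#' @export
set_parameter <- function(config, parameter, value) {
  stopifnot(inherits(config, "play_config"))
  if (!parameter %in% c(.config_fields, .config_aliases)) {
    stop("unknown parameter: ", parameter)
  }
  overrides <- attr(config, "overrides")
  overrides[[parameter]] <- value
  .play_config_build(config$variant, overrides)
}

#' @export
print.play_config <- function(x, ...) {
  cat("Play-as-practice model configuration (", x$variant, ")\n", sep = "")
  cat(sprintf("  grid: x = 0..%d, a = 0..%d, t = 0..%d (provisioning t < %d)\n",
              x$X, x$A, x$T, x$tau))
  cat(sprintf("  forage: cost %d, gain %d w.p. %.3g..%.3g, risk %.4g..%.4g, practice %.2g\n",
              x$c_f, x$y_e, x$y_z0, x$y_zA, x$m_f0, x$m_fA, x$s_f))
  cat(sprintf("  play:   cost %d, risk %.4g, practice %.2g\n",
              x$c_p, x$m_p, x$s_p))
  cat(sprintf("  rest:   cost %d, risk %.4g\n", x$c_r, x$m_r))
  cat(sprintf("  provisioning: %d w.p. %.3g; terminal: x_crit = %d, q = %.3g",
              x$w_e, x$w_z, x$x_crit, x$q))
  if (x$variant %in% c("model3a", "model3b")) {
    cat(sprintf(", omega_z = %.3g..%.3g", x$omega_z0, x$omega_zA))
  }
  cat("\n")
  invisible(x)
}

#' Linear interpolation of a rate between the ability endpoints
#'
#' Ability acts on the model's rates through straight-line interpolation:
#' a rate equals \code{v0} at \code{a = 0} and \code{vA} at \code{a = A}.
#' Used for the foraging predation risk (model 1), the foraging success
#' probability (model 2) and the terminal reproduction probability
#' (models 3a/3b).
#'
#' @param a integer ability level(s) in \code{0..A} (vectorized).
#' @param v0,vA endpoint values at \code{a = 0} and \code{a = A}.
#' @param A maximum ability.
#' @return \code{v0 + (vA - v0) * a / A}.
#' @examples
#' linear_ability_map(0, 0.005, 0.0002, 100)    # 0.005
#' linear_ability_map(100, 0.1, 0.9, 100)       # 0.9
#' @export
linear_ability_map <- function(a, v0, vA, A) {
  if (any(a < 0 | a > A)) stop("a out of range 0..A")
  if (A == 0) return(rep(v0, length(a)))  # degenerate single-level ability
  # convex-combination form: exact at both endpoints
  w <- a / A
  v0 * (1 - w) + vA * w
}

# per-timestep predation risk of an action, vectorized over a
.mortality <- function(config, action, a) {
  switch(action,
    forage = linear_ability_map(a, config$m_f0, config$m_fA, config$A),
    play = rep(config$m_p, length(a)),
    rest = rep(config$m_r, length(a))
  )
}

# foraging success probability, vectorized over a
.forage_success <- function(config, a) {
  linear_ability_map(a, config$y_z0, config$y_zA, config$A)
}

#' Terminal reward at the horizon
#'
#' The payoff at \code{t = T}: zero below the critical reserve level
#' \code{x_crit}, otherwise \code{(x/X)^q} scaled, in models 3a/3b, by the
#' ability-dependent reproduction probability
#' \code{linear_ability_map(a, omega_z0, omega_zA, A)}. With the default
#' \code{q = 0} the energy part is the binary success indicator.
#'
#' @param x integer reserve level(s) in \code{0..X} (vectorized).
#' @param a integer ability level(s) in \code{0..A} (vectorized, recycled).
#' @param config a \code{play_config}.
#' @return numeric payoff in \code{[0, 1]}.
#' @examples
#' cfg <- play_config("model1")
#' terminal_reward(149, 0, cfg)  # 0
#' terminal_reward(150, 0, cfg)  # 1
#' @export
terminal_reward <- function(x, a, config) {
  stopifnot(inherits(config, "play_config"))
  if (any(x < 0 | x > config$X)) stop("x out of range 0..X")
  if (any(a < 0 | a > config$A)) stop("a out of range 0..A")
  g <- if (config$q == 0) rep(1, length(x)) else (x / config$X)^config$q
  rho <- if (config$variant %in% c("model3a", "model3b")) {
    linear_ability_map(a, config$omega_z0, config$omega_zA, config$A)
  } else {
    1
  }
  ifelse(x >= config$x_crit, g * rho, 0)
}

# full (X+1) x (A+1) terminal matrix, rows x = 0..X, cols a = 0..A
.terminal_matrix <- function(config) {
  outer(0:config$X, 0:config$A, function(x, a) terminal_reward(x, a, config))
}
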