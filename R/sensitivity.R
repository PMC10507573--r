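#' One-at-a-time parameter sensitivity sweep
#'
#' For each value on the grid, rebuilds the configuration with the parameter
#' set to that value (all other parameters at the variant's defaults, with
#' variant-coupled endpoints re-derived; see \code{\link{set_parameter}}),
#' solves by backward induction, propagates the cohort forward from the
#' start state, and records the lifetime activity budget. The headline
#' summary is the range of parameter values over which play occupies at
#' least a threshold share (default 5\%) of lifetime activity.
#'
#' @param config a \code{\link{play_config}} supplying the variant and
#'   baseline parameters.
#' @param parameter field or alias name to sweep (e.g. \code{"m_p"},
#'   \code{"s_f"}, or aliases \code{"m_f"}, \code{"y_z"}, \code{"omega_z"}).
#' @param grid numeric vector of parameter values, in increasing order.
#' @param x_start,a_start forward-model start state (defaults 50 and 0, the
#'   sensitivity-analysis convention).
#' @param threshold qualifying lifetime play share (default 0.05).
#' @return An object of class \code{play_sweep}: list with \code{parameter},
#'   \code{grid}, \code{shares} (data frame \code{value}, \code{share_forage},
#'   \code{share_play}, \code{share_rest}, \code{qualifies}),
#'   \code{threshold}, \code{qualifying} (list of \code{c(min, max)}
#'   intervals from \code{\link{qualifying_range}}), and the start state.
#' @examples
#' cfg <- play_config("model1", X = 40, A = 5, T = 20, tau = 5, x_crit = 20)
#' sw <- oat_sweep(cfg, "m_p", c(0.0002, 0.01), x_start = 15)
#' sw$shares
#' @export
oat_sweep <- function(config, parameter, grid, x_start = 50, a_start = 0,
                      threshold = 0.05) {
  stopifnot(inherits(config, "play_config"), length(grid) >= 1)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  rows <- lapply(grid, function(v) {
    cfg_v <- set_parameter(config, parameter, v)
    traj <- forward_propagate(solve_policy(cfg_v), x_start, a_start)
    b <- suppressWarnings(lifetime_budget(traj))
    data.frame(value = v,
               share_forage = b[["forage"]],
               share_play = b[["play"]],
               share_rest = b[["rest"]])
  })
  shares <- do.call(rbind, rows)
  shares$qualifies <- !is.na(shares$share_play) &
    shares$share_play >= threshold
  out <- structure(
    list(parameter = parameter, grid = grid, shares = shares,
         threshold = threshold, x_start = as.integer(x_start),
         a_start = as.integer(a_start), variant = config$variant),
    class = "play_sweep"
  )
  out$qualifying <- qualifying_range(out, threshold)
  out
}

#' Parameter intervals where play meets the lifetime threshold
#'
#' Maximal runs of consecutive grid values whose lifetime play share is at
#' least the threshold, reported as closed \code{[min, max]} intervals of
#' grid values. Disjoint qualifying intervals (as arise e.g. when play is
#' optimal both for very poor and for very good practice efficiency) are
#' returned as separate elements.
#'
#' @param sweep a \code{\link{oat_sweep}} result.
#' @param threshold qualifying share; defaults to the sweep's own threshold.
#' @return list of numeric \code{c(min, max)} pairs; empty if no grid value
#'   qualifies.
#' @export
qualifying_range <- function(sweep, threshold = sweep$threshold) {
  stopifnot(inherits(sweep, "play_sweep"))
  ok <- !is.na(sweep$shares$share_play) &
    sweep$shares$share_play >= threshold
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) {
    c(sweep$grid[starts[i]], sweep$grid[ends[i]])
  })
}

#' @export
print.play_sweep <- function(x, ...) {
  cat(sprintf("One-at-a-time sweep of %s (%s), %d grid values in [%g, %g]\n",
              x$parameter, x$variant, length(x$grid), min(x$grid),
              max(x$grid)))
  if (length(x$qualifying)) {
    iv <- vapply(x$qualifying, function(r) sprintf("[%g, %g]", r[1], r[2]),
                 character(1))
    cat(sprintf("  play >= %.0f%% of lifetime on: %s\n", 100 * x$threshold,
                paste(iv, collapse = " and ")))
  } else {
    cat(sprintf("  play never reaches %.0f%% of lifetime on this grid\n",
                100 * x$threshold))
  }
  invisible(x)
}

# spans swept per parameter: the printed sensitivity spans where the
# qualifying range is unbounded ("all values"), otherwise a span generously
# covering the reported qualifying interval
.sweep_spans <- list(
  X = c(150, 600), A = c(10, 250), T = c(50, 350), tau = c(1, 100),
  w_e = c(0, 10), w_z = c(0, 1), y_e = c(1, 15), y_z = c(0, 1),
  c_f = c(1, 6), c_p = c(1, 14), c_r = c(-1, 3),
  m_f = c(0, 0.06), m_p = c(0, 0.06), m_r = c(0, 0.06),
  s_f = c(0, 1), s_p = c(0, 1), x_crit = c(1, 265), q = c(0, 2),
  omega_z = c(0, 1)
)

#' Default sweep grid for a parameter
#'
#' An evenly spaced grid over the span conventionally swept for each
#' parameter (integer-valued parameters get integer grids). Intended as a
#' convenience for \code{\link{oat_sweep}}; any explicit grid overrides it.
#'
#' @param parameter field or alias name.
#' @param n number of grid points (default 21).
#' @return numeric vector of length at most \code{n} (integer grids with a
#'   narrow span may have fewer distinct values).
#' @export
default_sweep_grid <- function(parameter, n = 21) {
  span <- .sweep_spans[[parameter]]
  if (is.null(span)) stop("no default sweep span for parameter: ", parameter)
  g <- seq(span[1], span[2], length.out = n)
  if (parameter %in% .integer_fields ||
      parameter %in% c("X", "A", "T", "tau")) {
    g <- unique(round(g))
  }
  g
}
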