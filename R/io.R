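#' Read or assemble a model configuration
#'
#' Builds a \code{\link{play_config}} from a flat \code{key = value} text
#' file, command-style overrides, or both. File keys are the configuration
#' field names (plus \code{variant} and the aliases \code{m_f}, \code{y_z},
#' \code{omega_z}); unspecified keys take the variant's defaults. Overrides
#' passed through \code{...} are applied last.
#'
#' @param path optional path to a \code{key = value} file; lines starting
#'   with \code{#} and blank lines are ignored.
#' @param variant model variant, used when the file does not set one
#'   (default \code{"model1"}).
#' @param ... named overrides applied after the file.
#' @return a \code{\link{play_config}}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("variant = model2", "tau = 40"), tf)
#' load_config(tf)$tau
#' @export
load_config <- function(path = NULL, variant = "model1", ...) {
  file_vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("cannot parse config line: ", ln)
      key <- trimws(kv[1L])
      val <- trimws(kv[2L])
      if (key == "variant") {
        variant <- val
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop("non-numeric value for ", key, ": ", val)
        file_vals[[key]] <- num
      }
    }
  }
  overrides <- utils::modifyList(file_vals, list(...))
  variant <- match.arg(variant, c("model1", "model2", "model3a", "model3b"))
  unknown <- setdiff(names(overrides), c(.config_fields, .config_aliases))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  .play_config_build(variant, overrides)
}

#' Write a configuration as a flat key = value file
#'
#' The inverse of \code{\link{load_config}}:
#' \code{load_config(write_play_config(cfg, path))} reproduces \code{cfg}.
#'
#' @param config a \code{\link{play_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_play_config <- function(config, path) {
  stopifnot(inherits(config, "play_config"))
  vals <- vapply(.config_fields, function(nm) {
    format(config[[nm]], digits = 17, scientific = FALSE)
  }, character(1))
  writeLines(c(paste("variant =", config$variant),
               paste(.config_fields, "=", vals)), path)
  invisible(path)
}

#' Export the choice function as a long-format CSV
#'
#' Columns \code{t} (0..T-1), \code{x} (1..X), \code{a} (0..A),
#' \code{choice} (forage/play/rest/none). The full grid is \code{T * X *
#' (A + 1)} rows; pass \code{a_levels} to export selected ability slices.
#'
#' @param solution a \code{\link{solve_policy}} result.
#' @param path output path.
#' @param a_levels ability levels to include (default: all).
#' @return \code{path}, invisibly.
#' @export
write_policy_csv <- function(solution, path,
                             a_levels = 0:solution$config$A) {
  stopifnot(inherits(solution, "play_solution"))
  cfg <- solution$config
  grid <- expand.grid(x = seq_len(cfg$X), a = a_levels,
                      t = 0:(cfg$T - 1L))
  code <- solution$policy[cbind(grid$x + 1L, grid$a + 1L, grid$t + 1L)]
  df <- data.frame(t = grid$t, x = grid$x, a = grid$a,
                   choice = as.character(.decode_action(code)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Export the value function as a long-format CSV
#'
#' Columns \code{t} (0..T), \code{x} (0..X), \code{a} (0..A), \code{value}.
#'
#' @inheritParams write_policy_csv
#' @return \code{path}, invisibly.
#' @export
write_value_csv <- function(solution, path,
                            a_levels = 0:solution$config$A) {
  stopifnot(inherits(solution, "play_solution"))
  cfg <- solution$config
  grid <- expand.grid(x = 0:cfg$X, a = a_levels, t = 0:cfg$T)
  df <- data.frame(
    t = grid$t, x = grid$x, a = grid$a,
    value = solution$value[cbind(grid$x + 1L, grid$a + 1L, grid$t + 1L)]
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' Export a cohort trajectory as CSV
#'
#' Columns \code{t}, \code{p_forage}, \code{p_play}, \code{p_rest},
#' \code{p_dead_cum}, \code{p_nopayoff_cum}, \code{mean_x}, \code{mean_a}
#' for decision epochs \code{t = 0..T-1} (proportions of the initial
#' cohort; the death column combines predation and starvation).
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  TT <- trajectory$config$T
  idx <- seq_len(TT)
  df <- data.frame(
    t = 0:(TT - 1L),
    p_forage = trajectory$activity[, "forage"],
    p_play = trajectory$activity[, "play"],
    p_rest = trajectory$activity[, "rest"],
    p_dead_cum = trajectory$cum_dead_predation[idx] +
      trajectory$cum_dead_starvation[idx],
    p_nopayoff_cum = trajectory$cum_no_payoff[idx],
    mean_x = trajectory$mean_x[idx],
    mean_a = trajectory$mean_a[idx]
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' Export a marginal state density as CSV
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @param axis \code{"energy"} or \code{"ability"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_density_csv <- function(trajectory, axis, path) {
  data.table::fwrite(state_density(trajectory, axis), path)
  invisible(path)
}

#' Export a sensitivity sweep as CSV
#'
#' Columns \code{parameter}, \code{value}, \code{share_forage},
#' \code{share_play}, \code{share_rest}, \code{qualifies}.
#'
#' @param sweep a \code{\link{oat_sweep}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "play_sweep"))
  df <- cbind(parameter = sweep$parameter, sweep$shares)
  df$qualifies <- as.integer(df$qualifies)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Export a Monte-Carlo summary as CSV
#'
#' Per-timestep empirical activity proportions in the trajectory-CSV layout,
#' plus constant \code{n} and \code{seed} columns.
#'
#' @param simulation a \code{\link{simulate_individuals}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_simulation_csv <- function(simulation, path) {
  stopifnot(inherits(simulation, "play_simulation"))
  TT <- simulation$config$T
  df <- data.frame(
    t = 0:(TT - 1L),
    p_forage = simulation$counts[, "forage"] / simulation$n,
    p_play = simulation$counts[, "play"] / simulation$n,
    p_rest = simulation$counts[, "rest"] / simulation$n,
    n = simulation$n,
    seed = simulation$seed
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, as flat \code{key = value} text, everything needed to reproduce
#' a run: the command, the fully resolved parameter values, the start state
#' and seed where applicable, the output paths, and the package version.
#'
#' @param path output path.
#' @param command short command description (e.g. \code{"solve"}).
#' @param config the \code{\link{play_config}} used.
#' @param outputs character vector of output paths.
#' @param extra named list of additional scalar entries (e.g. \code{seed},
#'   \code{x_start}).
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, command, config, outputs = character(0),
                               extra = list()) {
  stopifnot(inherits(config, "play_config"))
  vals <- vapply(.config_fields, function(nm) {
    format(config[[nm]], digits = 17, scientific = FALSE)
  }, character(1))
  lines <- c(
    paste("command =", command),
    paste("version =",
          as.character(utils::packageVersion("playsdp"))),
    paste("variant =", config$variant),
    paste(.config_fields, "=", vals)
  )
  for (nm in names(extra)) lines <- c(lines, paste(nm, "=", extra[[nm]]))
  if (length(outputs)) lines <- c(lines, paste("output =", outputs))
  writeLines(lines, path)
  invisible(path)
}
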