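#' Headline statistics of a propagated cohort
#'
#' Summary quantities of the ontogenetic time-course that characterise each
#' model variant's qualitative behaviour:
#' \describe{
#'   \item{\code{first_play_t}}{first decision epoch with play mass above
#'     the floor (\code{NA} if play never occurs).}
#'   \item{\code{play_only_prefix}}{number of consecutive epochs from
#'     \code{t = 0} in which forage and rest mass are both below the floor
#'     (play the only observed activity).}
#'   \item{\code{rest_only_suffix}}{number of consecutive epochs ending at
#'     \code{t = T-1} in which forage and play mass are both below the
#'     floor.}
#'   \item{\code{majority_max_ability_t}}{earliest epoch at which more than
#'     half of the active mass has ability \code{a = A} (\code{NA} if
#'     never).}
#'   \item{\code{min_play}, \code{max_play}}{extremes over epochs of the
#'     play proportion (fraction of the initial cohort).}
#'   \item{\code{mean_play_early}}{mean play proportion over the first 30
#'     epochs (the early-ontogeny plateau).}
#'   \item{\code{terminal_payoff}}{expected terminal payoff, equal to
#'     \code{U*(x_start, a_start, 0)}.}
#' }
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @param mass_floor probability mass below which an activity is treated as
#'   absent (default \code{1e-9}).
#' @return named list of the statistics above.
#' @export
trajectory_summary <- function(trajectory, mass_floor = 1e-9) {
  stopifnot(inherits(trajectory, "cohort_trajectory"))
  cfg <- trajectory$config
  TT <- cfg$T
  pf <- trajectory$activity[, "forage"]
  pp <- trajectory$activity[, "play"]
  pr <- trajectory$activity[, "rest"]

  first_play <- which(pp > mass_floor)[1L]
  only_play <- pf < mass_floor & pr < mass_floor
  prefix <- if (only_play[1L]) rle(only_play)$lengths[1L] else 0L
  only_rest <- pf < mass_floor & pp < mass_floor
  r <- rle(rev(only_rest))
  suffix <- if (r$values[1L]) r$lengths[1L] else 0L

  frac_max_a <- trajectory$mass[, cfg$A + 1L, ] |> colSums()
  frac_max_a <- ifelse(trajectory$active > 0,
                       frac_max_a / trajectory$active, 0)
  majority_t <- which(frac_max_a > 0.5)[1L]

  list(
    first_play_t = if (is.na(first_play)) NA_integer_ else first_play - 1L,
    play_only_prefix = as.integer(prefix),
    rest_only_suffix = as.integer(suffix),
    majority_max_ability_t = if (is.na(majority_t)) NA_integer_
                             else majority_t - 1L,
    min_play = min(pp),
    max_play = max(pp),
    mean_play_early = mean(pp[seq_len(min(30L, TT))]),
    terminal_payoff = trajectory$terminal_payoff
  )
}

#' Write the headline report of a forward run
#'
#' Key-value text file with the \code{\link{trajectory_summary}} statistics
#' and the lifetime activity budget.
#'
#' @param trajectory a \code{\link{forward_propagate}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(trajectory, path) {
  s <- trajectory_summary(trajectory)
  b <- suppressWarnings(lifetime_budget(trajectory))
  lines <- c(
    vapply(names(s), function(nm) paste(nm, "=", format(s[[nm]])),
           character(1)),
    paste("share_forage =", format(b[["forage"]])),
    paste("share_play =", format(b[["play"]])),
    paste("share_rest =", format(b[["rest"]]))
  )
  writeLines(lines, path)
  invisible(path)
}
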