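#' Learning curves and the law of practice
#'
#' A population learning curve aggregates player skill at each
#' experience level with the Hodges-Lehmann pseudomedian (the median of
#' all Walsh averages) and a confidence band from inverting the
#' one-sample signed-rank statistic. Population curves follow the law
#' of practice, `Skill = Skill0 * Experience^alpha`, which is linear on
#' the log10-log10 scale and fitted there by ordinary least squares.
#'
#' @name learning-curves
#' @keywords internal
NULL

#' Partition players into activity cohorts
#'
#' Players are binned by their total number of games into dyadic
#' intervals `[2^n, 2^(n+1))`. The learning curve of a cohort is meant
#' to use only each member's first `2^n` games, so every curve point
#' aggregates the full cohort.
#'
#' @param histories A player-history table from [build_histories()].
#' @param min_exponent Smallest dyadic exponent kept (default 3, i.e.
#'   the `[8, 16)` bin); players with fewer games are unassigned and
#'   dropped.
#' @param max_exponent Optional largest exponent kept.
#' @return A tibble with columns `player_id, total_games, exponent,
#'   cohort` (a label such as `"[8,16)"`) and `limit` (`2^exponent`,
#'   the number of leading games the cohort's curve uses).
#' @export
activity_cohorts <- function(histories, min_exponent = 3,
                             max_exponent = NULL) {
  stopifnot(min_exponent >= 0)
  totals <- tapply(histories$experience, histories$player_id, max)
  players <- names(totals)
  totals <- as.integer(totals)
  exponent <- floor(log2(pmax(totals, 1)))
  keep <- totals >= 2^min_exponent
  if (!is.null(max_exponent)) keep <- keep & exponent <= max_exponent
  exp_kept <- as.integer(exponent[keep])
  tibble::tibble(
    player_id = players[keep],
    total_games = totals[keep],
    exponent = exp_kept,
    cohort = sprintf("[%d,%d)", 2^exp_kept, 2^(exp_kept + 1)),
    limit = as.integer(2^exp_kept)
  )
}

#' Aggregate a population learning curve
#'
#' At each experience level, collects the post-game skill (`mu`) of
#' every selected player who reached that level and summarizes it with
#' the Hodges-Lehmann pseudomedian and the confidence interval obtained
#' by inverting the one-sample Wilcoxon signed-rank statistic
#' (`wilcox.test(..., conf.int = TRUE)`). Levels with a single
#' observation report the value itself with an absent (NA) interval.
#'
#' @param trajectories A trajectory table from [rate_history()].
#' @param players Optional character vector restricting the curve to
#'   those players (e.g. one cohort).
#' @param max_experience Optional cap: use experience levels up to this
#'   value (a cohort's `limit`).
#' @param experiences Optional integer vector of experience levels to
#'   report; default, all levels present.
#' @param conf_level Confidence level of the band. Default 0.95.
#' @return A tibble with columns `experience, n_obs, pseudomedian,
#'   ci_low, ci_high`, experience strictly increasing.
#' @export
aggregate_curve <- function(trajectories, players = NULL,
                            max_experience = NULL, experiences = NULL,
                            conf_level = 0.95) {
  tr <- trajectories
  if (!is.null(players)) tr <- tr[tr$player_id %in% players, , drop = FALSE]
  if (!is.null(max_experience)) {
    tr <- tr[tr$experience <= max_experience, , drop = FALSE]
  }
  if (nrow(tr) == 0) stop("no trajectory rows selected")
  if (is.null(experiences)) experiences <- sort(unique(tr$experience))
  skills <- split(tr$mu, tr$experience)
  rows <- lapply(as.character(experiences), function(e) {
    x <- skills[[e]]
    if (is.null(x)) return(NULL)
    n <- length(x)
    if (n < 2) {
      return(data.frame(experience = as.integer(e), n_obs = n,
                        pseudomedian = x[1], ci_low = NA_real_,
                        ci_high = NA_real_))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, conf.int = TRUE, conf.level = conf_level)
    )
    data.frame(experience = as.integer(e), n_obs = n,
               pseudomedian = unname(wt$estimate),
               ci_low = wt$conf.int[1], ci_high = wt$conf.int[2])
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out[order(out$experience), , drop = FALSE]
}

#' Fit the law of practice
#'
#' Ordinary least squares of `log10(skill)` on `log10(experience)`
#' over an aggregated learning curve: the slope is the learning rate
#' `alpha`, and `10^intercept` is `Skill0`, the population skill after
#' the first game.
#'
#' @param curve A curve tibble from [aggregate_curve()] (columns
#'   `experience` and `pseudomedian`), or any data frame with those
#'   columns.
#' @param experience_range Optional `c(lo, hi)` restricting the fitted
#'   experience window.
#' @return An object of class `power_law_fit`: a list with `alpha`,
#'   `alpha_se`, `skill0`, `intercept`, `intercept_se`, `r_squared`,
#'   `residual_se` and `n`.
#' @export
fit_power_law <- function(curve, experience_range = NULL) {
  d <- curve
  if (!is.null(experience_range)) {
    d <- d[d$experience >= experience_range[1] &
             d$experience <= experience_range[2], , drop = FALSE]
  }
  if (nrow(d) < 2) stop("need at least two curve points to fit")
  if (any(d$pseudomedian <= 0)) {
    stop("skill must be positive on the fitted range (log scale)")
  }
  fit <- stats::lm(log10(pseudomedian) ~ log10(experience), data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    alpha = unname(co[2, 1]),
    alpha_se = unname(co[2, 2]),
    intercept = unname(co[1, 1]),
    intercept_se = unname(co[1, 2]),
    skill0 = 10^unname(co[1, 1]),
    r_squared = sm$r.squared,
    residual_se = sm$sigma,
    n = nrow(d)
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Law-of-practice fit (log10-log10 OLS)\n")
  cat(sprintf("  alpha  = %.4f (SE %.4f)\n", x$alpha, x$alpha_se))
  cat(sprintf("  Skill0 = %.2f tsp (intercept %.4f, SE %.4f)\n",
              x$skill0, x$intercept, x$intercept_se))
  cat(sprintf("  R^2 = %.4f over %d curve points\n", x$r_squared, x$n))
  invisible(x)
}

#' Compare two skill samples at one experience level
#'
#' Two-sample Wilcoxon rank-sum test of the skill values of two player
#' groups at the same experience level: exact when the combined sample
#' has at most 50 observations (and no ties), the normal approximation
#' with tie correction otherwise.
#'
#' @param skill_a,skill_b Numeric vectors of skills for the two groups.
#' @param conf_level Confidence level passed through. Default 0.95.
#' @return The `htest` object from [stats::wilcox.test()] (two-sided).
#' @export
compare_curves <- function(skill_a, skill_b, conf_level = 0.95) {
  exact <- (length(skill_a) + length(skill_b)) <= 50
  suppressWarnings(
    stats::wilcox.test(skill_a, skill_b, exact = exact, correct = TRUE,
                       conf.level = conf_level)
  )
}
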