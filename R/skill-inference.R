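#' Gaussian skill beliefs
#'
#' A rating is a Gaussian belief over a player's latent skill,
#' parameterized by a mean `mu` and a deviation `sigma` (both in
#' TrueSkill points, tsp). New players start at the conventional prior
#' `mu = 25`, `sigma = 25/3`. Game outcomes are driven by performances:
#' each player's performance in a game is Normal(skill, beta^2), a team's
#' performance is the sum of its members' performances, and the team
#' with the higher performance wins.
#'
#' @param mu Skill-belief mean(s), tsp. Default 25.
#' @param sigma Skill-belief deviation(s), tsp; must be positive.
#'   Default 25/3.
#' @param player_id Optional player identifier(s).
#' @return A tibble with columns `mu`, `sigma` (and `player_id` when
#'   given), one row per rating.
#' @examples
#' rating()                      # the default prior
#' rating(c(30, 20), c(5, 5))   # a two-player team
#' @export
rating <- function(mu = 25, sigma = 25 / 3, player_id = NULL) {
  n <- max(length(mu), length(sigma))
  mu <- rep_len(as.numeric(mu), n)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  out <- tibble::tibble(mu = mu, sigma = sigma)
  if (!is.null(player_id)) out$player_id <- rep_len(as.character(player_id), n)
  out
}

as_rating_df <- function(x, arg = "team") {
  if (!is.data.frame(x) || !all(c("mu", "sigma") %in% names(x))) {
    stop(arg, " must be a data frame with columns mu and sigma ",
         "(see rating())")
  }
  if (nrow(x) < 1) stop(arg, " must contain at least one rating")
  if (any(x$sigma < 0)) stop(arg, ": sigma must be nonnegative")
  x
}

# phi(t)/Phi(t) and its companion w(t) = v(t) (v(t) + t), the mean- and
# variance-correction factors of the truncated-Gaussian moment match.
# For t < -5 the direct ratio loses precision (phi and Phi both
# underflow around t ~ -38), so the tail is evaluated in log space,
# where pnorm's log-scale tail expansion is accurate to full double
# precision (v(t) ~ -t + 1/(-t) far in the left tail).
gauss_v <- function(t) {
  out <- numeric(length(t))
  lo <- t < -5
  out[!lo] <- stats::dnorm(t[!lo]) / stats::pnorm(t[!lo])
  if (any(lo)) {
    out[lo] <- exp(stats::dnorm(t[lo], log = TRUE) -
                     stats::pnorm(t[lo], log.p = TRUE))
  }
  out
}

gauss_w <- function(t) {
  v <- gauss_v(t)
  v * (v + t)
}

#' Team performance distribution
#'
#' The performance of a team is the sum of its members' performances,
#' hence Gaussian with mean `sum(mu)` and variance
#' `sum(beta^2 + sigma^2)`.
#'
#' @param team A rating tibble (one row per member, see [rating()]).
#' @param beta Performance noise deviation, tsp. Default 25/6.
#' @return A list with elements `mean` and `variance`.
#' @export
team_performance <- function(team, beta = 25 / 6) {
  team <- as_rating_df(team)
  stopifnot(beta > 0)
  list(mean = sum(team$mu),
       variance = sum(beta^2 + team$sigma^2))
}

#' Expected difference and total variance between two teams
#'
#' The difference of two team performances is Gaussian with mean
#' `delta` (team a minus team b means) and variance `theta`, the total
#' variance `sum(beta^2 + sigma_i^2)` over every player on either team.
#'
#' @param team_a,team_b Rating tibbles for the two teams.
#' @inheritParams team_performance
#' @return A list with elements `delta` and `theta`.
#' @export
difference_summary <- function(team_a, team_b, beta = 25 / 6) {
  team_a <- as_rating_df(team_a, "team_a")
  team_b <- as_rating_df(team_b, "team_b")
  stopifnot(beta > 0)
  if ("player_id" %in% names(team_a) && "player_id" %in% names(team_b)) {
    shared <- intersect(team_a$player_id, team_b$player_id)
    if (length(shared) > 0) {
      stop("player(s) on both teams: ", paste(shared, collapse = ", "))
    }
  }
  list(delta = sum(team_a$mu) - sum(team_b$mu),
       theta = sum(beta^2 + team_a$sigma^2) + sum(beta^2 + team_b$sigma^2))
}

#' Probability that one team beats another
#'
#' `Phi(delta / sqrt(theta))`: the probability that the performance
#' difference (Gaussian with mean `delta`, variance `theta`) is
#' positive. Complements sum to one; two teams with identical ratings
#' have probability 1/2 each.
#'
#' @inheritParams difference_summary
#' @return A probability in (0, 1).
#' @export
win_probability <- function(team_a, team_b, beta = 25 / 6) {
  d <- difference_summary(team_a, team_b, beta)
  stats::pnorm(d$delta / sqrt(d$theta))
}

#' Moments of the exact single-player posterior
#'
#' After a two-team game, the exact posterior for one player's skill is
#' proportional to `N(s; mu, sigma^2) * Phi(arg / sqrt(var_rest))` with
#' `arg = delta_rest + s` for a winner and `arg = delta_rest - s` for a
#' loser, where `delta_rest` is the expected winner-minus-loser
#' difference with the player's own mean removed (`delta - mu` for a
#' winner, `delta + mu` for a loser) and `var_rest = theta - sigma^2`
#' is the total variance contributed by everything except the player's
#' own skill belief. This function computes the posterior's first two
#' moments by adaptive quadrature; it is the independent oracle for
#' [moment_matched_update()].
#'
#' @param mu,sigma Prior belief for the player (tsp).
#' @param delta_rest Expected performance difference excluding the
#'   player's own mean (tsp), oriented winner minus loser.
#' @param var_rest Total variance excluding the player's own belief
#'   variance (tsp^2); must be positive.
#' @param won Logical: did the player's team win?
#' @return A list with elements `mean` and `variance`.
#' @export
exact_posterior_moments <- function(mu, sigma, delta_rest, var_rest,
                                    won = TRUE) {
  stopifnot(sigma > 0, var_rest > 0)
  sign <- if (won) 1 else -1
  root <- sqrt(var_rest)
  # work on the standardized scale z = (s - mu)/sigma, in log space:
  # when the likelihood step is far in the prior's tail the posterior
  # mass is minuscule in absolute terms, so the integrand is rescaled
  # by its mode before quadrature
  logf <- function(z) {
    stats::dnorm(z, log = TRUE) +
      stats::pnorm((delta_rest + sign * (mu + sigma * z)) / root,
                   log.p = TRUE)
  }
  opt <- stats::optimize(logf, c(-15, 15), maximum = TRUE, tol = 1e-8)
  peak <- opt$objective
  # the posterior's z-scale spread is at most the prior's, so +-12
  # around the mode holds all mass while keeping the peak centred
  # where the adaptive rule samples densely
  lo <- opt$maximum - 12
  hi <- opt$maximum + 12
  quad <- function(k) {
    r <- NULL
    for (tol in c(1e-12, 1e-10, 1e-8)) {
      r <- tryCatch(
        stats::integrate(function(z) z^k * exp(logf(z) - peak), lo, hi,
                         rel.tol = tol, abs.tol = tol,
                         subdivisions = 400L),
        error = function(e) e
      )
      if (!inherits(r, "error")) break
    }
    if (inherits(r, "error")) {
      stop("posterior integral failed: ", conditionMessage(r),
           call. = FALSE)
    }
    if (!is.finite(r$value)) stop("posterior integral is not finite")
    r$value
  }
  z0 <- quad(0)
  z1 <- quad(1) / z0
  z2 <- quad(2) / z0
  list(mean = mu + sigma * z1,
       variance = sigma^2 * (z2 - z1^2))
}

# Closed-form moment-matched two-team update on plain vectors.
# delta is oriented winner minus loser; c2 = theta.
ts_pair_update <- function(mu_w, s2_w, mu_l, s2_l, beta) {
  c2 <- sum(beta^2 + s2_w) + sum(beta^2 + s2_l)
  cc <- sqrt(c2)
  t <- (sum(mu_w) - sum(mu_l)) / cc
  v <- gauss_v(t)
  w <- gauss_w(t)
  list(mu_w = mu_w + s2_w / cc * v,
       s2_w = s2_w * (1 - s2_w / c2 * w),
       mu_l = mu_l - s2_l / cc * v,
       s2_l = s2_l * (1 - s2_l / c2 * w))
}

#' Moment-matched rating update for a two-team game
#'
#' Replaces the exact non-Gaussian posterior of every participant with
#' the Gaussian matching its first two moments (the Gaussian of minimum
#' Kullback-Leibler divergence). With `c = sqrt(theta)` and
#' `t = delta / c` oriented winner minus loser, each winner gains
#' `(sigma_i^2 / c) * v(t)` in mean, each loser loses
#' `(sigma_j^2 / c) * v(t)`, and every deviation shrinks by the factor
#' `sqrt(1 - (sigma^2 / c^2) * w(t))`, where `v(t) = phi(t)/Phi(t)` and
#' `w(t) = v(t)(v(t) + t)`. Winner means never decrease, loser means
#' never increase, and every `sigma` strictly decreases (unless already
#' zero).
#'
#' @param winners,losers Rating tibbles for the winning and losing team.
#' @inheritParams team_performance
#' @return A list with updated `winners` and `losers` rating tibbles.
#' @export
moment_matched_update <- function(winners, losers, beta = 25 / 6) {
  winners <- as_rating_df(winners, "winners")
  losers <- as_rating_df(losers, "losers")
  stopifnot(beta > 0)
  if (all(winners$sigma == 0) && all(losers$sigma == 0)) {
    warning("all ratings have sigma = 0; update is a no-op")
    return(list(winners = winners, losers = losers))
  }
  up <- ts_pair_update(winners$mu, winners$sigma^2,
                       losers$mu, losers$sigma^2, beta)
  winners$mu <- up$mu_w
  winners$sigma <- sqrt(up$s2_w)
  losers$mu <- up$mu_l
  losers$sigma <- sqrt(up$s2_l)
  list(winners = winners, losers = losers)
}

#' Rating update for a ranked multi-team game
#'
#' Ranked games with more than two teams are handled by applying the
#' two-team update sequentially to each adjacently ranked pair (first
#' versus second, second versus third, ...), using the ratings as
#' updated so far. This is an approximation to the full joint posterior
#' over the team ranking; with two teams it reduces exactly to
#' [moment_matched_update()].
#'
#' @param teams A list of rating tibbles, in team-position order.
#' @param outcome An integer permutation of the team positions, winner
#'   first. Ties are not allowed.
#' @inheritParams team_performance
#' @return A list of updated rating tibbles, in the original team order.
#' @export
multi_team_update <- function(teams, outcome, beta = 25 / 6) {
  stopifnot(is.list(teams), length(teams) >= 2)
  teams <- lapply(teams, as_rating_df)
  outcome <- as.integer(outcome)
  if (!setequal(outcome, seq_along(teams)) ||
      length(outcome) != length(teams)) {
    stop("outcome must be a permutation of the team positions (no ties)")
  }
  for (k in seq_len(length(outcome) - 1)) {
    a <- outcome[k]
    b <- outcome[k + 1]
    up <- moment_matched_update(teams[[a]], teams[[b]], beta)
    teams[[a]] <- up$winners
    teams[[b]] <- up$losers
  }
  teams
}

#' Elo expected score
#'
#' Probability that a player with scalar skill `si` beats one with
#' `sj`, under the shared performance model with noise deviation
#' `beta`: `Phi((si - sj) / (sqrt(2) * beta))`.
#'
#' @param si,sj Scalar skills.
#' @param beta Performance noise deviation; must be positive.
#' @return A probability in (0, 1).
#' @export
elo_win_probability <- function(si, sj, beta = 25 / 6) {
  stopifnot(beta > 0)
  stats::pnorm((si - sj) / (sqrt(2) * beta))
}

#' Elo rating update
#'
#' The update is `K * Delta` where `Delta` is the signed outcome
#' surprise: direction (+1 when i wins, -1 when j wins) times one minus
#' the probability that was assigned to the observed result. The pair
#' update is zero-sum.
#'
#' @inheritParams elo_win_probability
#' @param i_wins Logical: did player i win?
#' @param K Maximum points disputed per game; must be positive.
#' @return A named numeric vector `c(si, sj)` with the updated skills.
#' @export
elo_update <- function(si, sj, i_wins, K = 32, beta = 25 / 6) {
  stopifnot(K > 0, is.logical(i_wins), length(i_wins) == 1)
  p_i <- elo_win_probability(si, sj, beta)
  p_obs <- if (i_wins) p_i else 1 - p_i
  delta <- (if (i_wins) 1 else -1) * (1 - p_obs)
  c(si = si + K * delta, sj = sj - K * delta)
}

#' Site point-system delta
#'
#' The game platform's own point exchange: the winner takes
#' `min((loser score / winner score) * 20, 100)` points from the loser.
#' It is a crude skill proxy, provided for completeness.
#'
#' @param winner_score,loser_score Positive site scores.
#' @return Points exchanged, in (0, 100].
#' @export
site_points_delta <- function(winner_score, loser_score) {
  if (any(winner_score <= 0) || any(loser_score <= 0)) {
    stop("scores must be positive")
  }
  pmin(loser_score / winner_score * 20, 100)
}

#' Rate a full game history
#'
#' Runs the moment-matched Bayesian update over a chronological game
#' stream. Every new player is initialized at the prior
#' `(mu0, sigma0)`; after each game all of its participants are
#' updated, and the post-game belief is recorded against the player's
#' running experience index. The skill scalar used by all downstream
#' analyses is the post-game posterior mean `mu`.
#'
#' @param games A validated game-history tibble (see [read_games()]).
#' @param mu0,sigma0 Prior mean and deviation for new players.
#'   Defaults 25 and 25/3.
#' @param beta Performance noise deviation. Default 25/6.
#' @param tau Additive dynamics deviation applied to every
#'   participant's belief before each game (`sigma^2 + tau^2`).
#'   Default 0 (no skill dynamics).
#' @return A tibble of trajectories with columns `player_id, game_id,
#'   seq, experience, mu, sigma`, one row per player-game in stream
#'   order.
#' @export
rate_history <- function(games, mu0 = 25, sigma0 = 25 / 3, beta = 25 / 6,
                         tau = 0) {
  validate_games(games)
  stopifnot(sigma0 > 0, beta > 0, tau >= 0)
  n_games <- nrow(games)
  players <- unique(unlist(games$teams, use.names = FALSE))
  np <- length(players)
  if (n_games == 0 || np == 0) {
    return(tibble::tibble(player_id = character(), game_id = character(),
                          seq = integer(), experience = integer(),
                          mu = numeric(), sigma = numeric()))
  }
  # integer-indexed team membership, resolved once up front
  teams_idx <- lapply(games$teams, function(ts) {
    lapply(ts, function(p) match(p, players))
  })
  mu <- rep(mu0, np)
  s2 <- rep(sigma0^2, np)
  exp_count <- integer(np)
  total_rows <- sum(vapply(teams_idx, function(ts) {
    sum(lengths(ts))
  }, numeric(1)))
  out_player <- integer(total_rows)
  out_game <- integer(total_rows)
  out_exp <- integer(total_rows)
  out_mu <- numeric(total_rows)
  out_sigma <- numeric(total_rows)
  pos <- 0L
  tau2 <- tau^2
  for (g in seq_len(n_games)) {
    ts <- teams_idx[[g]]
    o <- games$outcome[[g]]
    all_idx <- unlist(ts, use.names = FALSE)
    if (tau2 > 0) s2[all_idx] <- s2[all_idx] + tau2
    if (length(ts) == 2) {
      w <- ts[[o[1]]]
      l <- ts[[o[2]]]
      up <- ts_pair_update(mu[w], s2[w], mu[l], s2[l], beta)
      mu[w] <- up$mu_w; s2[w] <- up$s2_w
      mu[l] <- up$mu_l; s2[l] <- up$s2_l
    } else {
      for (k in seq_len(length(o) - 1)) {
        w <- ts[[o[k]]]
        l <- ts[[o[k + 1]]]
        up <- ts_pair_update(mu[w], s2[w], mu[l], s2[l], beta)
        mu[w] <- up$mu_w; s2[w] <- up$s2_w
        mu[l] <- up$mu_l; s2[l] <- up$s2_l
      }
    }
    exp_count[all_idx] <- exp_count[all_idx] + 1L
    rows <- pos + seq_along(all_idx)
    out_player[rows] <- all_idx
    out_game[rows] <- g
    out_exp[rows] <- exp_count[all_idx]
    out_mu[rows] <- mu[all_idx]
    out_sigma[rows] <- sqrt(s2[all_idx])
    pos <- pos + length(all_idx)
  }
  tibble::tibble(
    player_id = players[out_player],
    game_id = games$game_id[out_game],
    seq = games$seq[out_game],
    experience = out_exp,
    mu = out_mu,
    sigma = out_sigma
  )
}
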