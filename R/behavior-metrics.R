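#' Grouping-behaviour metrics
#'
#' Three per-player fractions summarize grouping behaviour:
#'
#' * **team-oriented behaviour (TOB)** — team games played divided by
#'   games played;
#' * **loyalty** — games played with the most recurrent teammate
#'   divided by team games played (undefined without team games);
#' * **faithfulness** — games played with the most recurrent teammate
#'   divided by all games played, identically `loyalty * TOB`.
#'
#' A *partner* is any teammate sharing the player's team in a game; a
#' game with k teammates contributes one game to each of the k partner
#' counts.
#'
#' @name behavior-metrics
#' @keywords internal
NULL

# All (focal, partner) teammate pairs from a player-history table,
# with the focal player's experience at that game. Expands the
# `teammates` list column, so it works on any subset of history rows
# (e.g. a single player, or a prefix).
partner_pairs <- function(histories) {
  counts <- lengths(histories$teammates)
  focal <- rep(seq_len(nrow(histories)), counts)
  tibble::tibble(
    player_id = histories$player_id[focal],
    partner_id = as.character(unlist(histories$teammates,
                                     use.names = FALSE)),
    experience = histories$experience[focal]
  )
}

#' Behaviour profiles for every player
#'
#' Computes per-player game counts and the TOB / loyalty / faithfulness
#' fractions, optionally restricted to each player's first `upto`
#' games, plus the population classifications and the eligibility flag
#' (at least four team games played).
#'
#' @param histories A player-history table from [build_histories()].
#' @param upto Optional experience cutoff: use only each player's first
#'   `upto` games. `NULL` (default) uses the whole history.
#' @return A tibble with columns `player_id, games_played, team_games,
#'   max_partner_games, tob, loyalty, faithfulness, tob_class,
#'   loyalty_class, eligible`. `loyalty` is `NA` (undefined, not zero)
#'   for players without team games.
#' @export
behavior_profiles <- function(histories, upto = NULL) {
  h <- histories
  if (!is.null(upto)) {
    stopifnot(upto >= 1)
    h <- h[h$experience <= upto, , drop = FALSE]
  }
  players <- unique(h$player_id)
  pid <- factor(h$player_id, levels = players)
  games_played <- as.integer(tabulate(pid, nbins = length(players)))
  team_games <- as.integer(rowsum(as.numeric(h$team_game), pid)[, 1])
  pairs <- partner_pairs(h)
  max_partner <- integer(length(players))
  if (nrow(pairs) > 0) {
    counts <- table(factor(pairs$player_id, levels = players),
                    pairs$partner_id)
    max_partner <- as.integer(apply(counts, 1, max))
  }
  tob <- team_games / games_played
  loyalty <- ifelse(team_games > 0, max_partner / team_games, NA_real_)
  faithfulness <- max_partner / games_played
  tibble::tibble(
    player_id = players,
    games_played = games_played,
    team_games = team_games,
    max_partner_games = max_partner,
    tob = tob,
    loyalty = loyalty,
    faithfulness = faithfulness,
    tob_class = classify_tob(tob),
    loyalty_class = classify_loyalty(loyalty),
    eligible = is_eligible(team_games)
  )
}

#' Behaviour profile of a single player
#'
#' @param history The rows of one player from [build_histories()].
#' @inheritParams behavior_profiles
#' @return A one-row profile tibble (see [behavior_profiles()]).
#' @export
behavior_profile <- function(history, upto = NULL) {
  if (nrow(history) == 0) stop("history is empty")
  if (length(unique(history$player_id)) != 1) {
    stop("history must contain a single player; see behavior_profiles()")
  }
  behavior_profiles(history, upto = upto)
}

#' Running behaviour covariates at every game
#'
#' For each player-game row, the TOB, loyalty and faithfulness values
#' computed over the player's history *up to and including* that game.
#' This is the default covariate convention for the cross-sectional and
#' mixed models: the behaviour a player has exhibited by the time the
#' skill is measured.
#'
#' @inheritParams behavior_profiles
#' @return `histories` with additional columns `run_team_games,
#'   run_max_partner, run_tob, run_loyalty, run_faithfulness`.
#' @export
running_profiles <- function(histories) {
  h <- histories
  n <- nrow(h)
  if (n == 0) {
    h$run_team_games <- integer()
    h$run_max_partner <- integer()
    h$run_tob <- numeric()
    h$run_loyalty <- numeric()
    h$run_faithfulness <- numeric()
    return(h)
  }
  players <- unique(h$player_id)
  pid <- factor(h$player_id, levels = players)
  ord <- order(pid, h$experience)
  team_cum <- integer(n)
  team_cum[ord] <- unlist(lapply(split(as.integer(h$team_game[ord]), pid[ord]),
                                 cumsum), use.names = FALSE)
  # running count of games with the (currently) most recurrent teammate
  pairs <- partner_pairs(h)
  run_max <- integer(n)
  if (nrow(pairs) > 0) {
    pkey <- paste(pairs$player_id, pairs$partner_id, sep = "\r")
    qord <- order(pkey, pairs$experience)
    cnt <- integer(nrow(pairs))
    cnt[qord] <- sequence(rle(pkey[qord])$lengths)
    # cnt: per pair row, the running count of games the focal player
    # has played with that partner (at that row's experience)
    by_player <- split(seq_len(nrow(pairs)),
                       factor(pairs$player_id, levels = players))
    rows_of <- split(seq_len(n), pid)
    for (p in seq_along(players)) {
      pr <- by_player[[p]]
      if (length(pr) == 0) next
      rows <- rows_of[[p]]
      rows <- rows[order(h$experience[rows])]
      vals <- numeric(length(rows))
      best <- tapply(cnt[pr], pairs$experience[pr], max)
      vals[as.integer(names(best))] <- best
      run_max[rows] <- as.integer(cummax(vals))
    }
  }
  h$run_team_games <- team_cum
  h$run_max_partner <- run_max
  h$run_tob <- team_cum / h$experience
  h$run_loyalty <- ifelse(team_cum > 0, run_max / team_cum, NA_real_)
  h$run_faithfulness <- run_max / h$experience
  h
}

#' Classify team-oriented behaviour
#'
#' Half-open population bins: `strong` for TOB in (0.8, 1], `medium`
#' for (0.4, 0.6], `weak` for (0, 0.2], `none` for TOB = 0 (players
#' without team games), and `other` for values in the gaps. Note the
#' boundaries: TOB = 0.8 is *not* strong, TOB = 0.2 *is* weak.
#'
#' @param tob Numeric vector of TOB values in \[0, 1\].
#' @return A factor with levels `strong, medium, weak, other, none`.
#' @export
classify_tob <- function(tob) {
  if (any(tob < 0 | tob > 1, na.rm = TRUE)) stop("tob must be in [0, 1]")
  out <- rep(NA_character_, length(tob))
  ok <- !is.na(tob)
  out[ok] <- "other"
  out[ok & tob == 0] <- "none"
  out[ok & tob > 0 & tob <= 0.2] <- "weak"
  out[ok & tob > 0.4 & tob <= 0.6] <- "medium"
  out[ok & tob > 0.8 & tob <= 1] <- "strong"
  factor(out, levels = c("strong", "medium", "weak", "other", "none"))
}

#' Classify loyalty
#'
#' `loyal` when loyalty > 0.5, `casual` when loyalty <= 0.2 (the
#' boundary is casual), `other` in between. Undefined loyalty (no team
#' games) stays `NA`.
#'
#' @param loyalty Numeric vector of loyalty values in \[0, 1\] (may
#'   contain `NA`).
#' @return A factor with levels `loyal, casual, other`.
#' @export
classify_loyalty <- function(loyalty) {
  if (any(loyalty < 0 | loyalty > 1, na.rm = TRUE)) {
    stop("loyalty must be in [0, 1]")
  }
  out <- rep(NA_character_, length(loyalty))
  ok <- !is.na(loyalty)
  out[ok] <- "other"
  out[ok & loyalty > 0.5] <- "loyal"
  out[ok & loyalty <= 0.2] <- "casual"
  factor(out, levels = c("loyal", "casual", "other"))
}

#' Analysis eligibility
#'
#' Players with fewer than four team games are excluded from the
#' behaviour analyses.
#'
#' @param team_games Integer vector of team-game counts.
#' @return Logical vector: `TRUE` when `team_games >= 4`.
#' @export
is_eligible <- function(team_games) {
  team_games >= 4
}
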