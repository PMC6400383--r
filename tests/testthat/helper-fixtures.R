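# Build a game tibble from a list of games, each a list of character
# vectors (teams); `winners` gives the winning team position per game.
game_tbl <- function(teams, winners, seqs = seq_along(teams) - 1L) {
  outcome <- lapply(seq_along(teams), function(i) {
    w <- winners[i]
    c(w, setdiff(seq_along(teams[[i]]), w))
  })
  tibble::tibble(
    game_id = paste0("g", seq_along(teams)),
    seq = as.integer(seqs),
    teams = teams,
    outcome = lapply(outcome, as.integer)
  )
}

# The canonical worked example: player "x" plays 8 games, 4 of them team
# games, with partner counts {a: 3, b: 1}; opponents are singletons or
# the pair (c, d). x wins every game.
eight_game_history <- function() {
  teams <- list(
    list(c("x"), c("o")), list(c("x"), c("o")),
    list(c("x"), c("o")), list(c("x"), c("o")),
    list(c("x", "a"), c("c", "d")), list(c("x", "a"), c("c", "d")),
    list(c("x", "a"), c("c", "d")), list(c("x", "b"), c("c", "d"))
  )
  game_tbl(teams, winners = rep(1L, 8))
}

# A small synthetic world for property tests.
small_config <- function(seed = 1, ...) {
  args <- list(n_players = 60, games_total = 1500, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Sequential rater whose per-player updates come from adaptive
# quadrature of the exact posterior — the independent oracle route for
# rate_history()'s closed-form moment matching.
quadrature_rate_history <- function(games, mu0 = 25, sigma0 = 25 / 3,
                                    beta = 25 / 6) {
  players <- unique(unlist(games$teams, use.names = FALSE))
  mu <- stats::setNames(rep(mu0, length(players)), players)
  sigma <- stats::setNames(rep(sigma0, length(players)), players)
  for (g in seq_len(nrow(games))) {
    o <- games$outcome[[g]]
    w <- games$teams[[g]][[o[1]]]
    l <- games$teams[[g]][[o[2]]]
    delta <- sum(mu[w]) - sum(mu[l])
    theta <- sum(beta^2 + sigma[c(w, l)]^2)
    new_mu <- mu
    new_sigma <- sigma
    for (p in c(w, l)) {
      won <- p %in% w
      dr <- if (won) delta - mu[p] else delta + mu[p]
      mom <- exact_posterior_moments(mu[p], sigma[p], dr,
                                     theta - sigma[p]^2, won)
      new_mu[p] <- mom$mean
      new_sigma[p] <- sqrt(mom$variance)
    }
    mu[c(w, l)] <- new_mu[c(w, l)]
    sigma[c(w, l)] <- new_sigma[c(w, l)]
  }
  tibble::tibble(player_id = players, mu = unname(mu), sigma = unname(sigma))
}

# Random two-team streams (mix of 1v1 and 2v2) for differential tests.
random_two_team_games <- function(n_games, n_players = 8, seed = 1) {
  withr::with_seed(seed, {
    ids <- paste0("p", seq_len(n_players))
    teams <- vector("list", n_games)
    winners <- integer(n_games)
    for (g in seq_len(n_games)) {
      if (stats::runif(1) < 0.5) {
        pick <- sample(ids, 2)
        teams[[g]] <- list(pick[1], pick[2])
      } else {
        pick <- sample(ids, 4)
        teams[[g]] <- list(pick[1:2], pick[3:4])
      }
      winners[g] <- sample(1:2, 1)
    }
    game_tbl(teams, winners)
  })
}
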