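#' Synthetic game-history generator
#'
#' An agent-based simulator producing chronological game histories with
#' the statistical structure the analysis pipeline assumes: latent
#' skills that grow as a power law of experience and are modulated by
#' grouping-behaviour covariates on the log10 scale, team-versus-solo
#' game choice with controllable team-oriented behaviour, partner
#' repetition with controllable loyalty, and outcomes drawn from the
#' additive Gaussian team-performance model (higher summed performance
#' wins).
#'
#' @name synthetic-data
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Bundles every knob of the synthetic world. The default skill-growth
#' and effect coefficients (all on the log10-skill scale) describe a
#' population whose baseline follows `Skill = 26 * Experience^0.016`
#' with a per-player random intercept, a cross-sectional loyalty /
#' TOB / faithfulness effect pattern of about (+0.8, -1.0, +3.7) tsp at
#' 100 games of experience, and experience interactions that weaken the
#' faithfulness boost while turning the TOB contribution positive as
#' experience accumulates.
#'
#' @param n_players Number of players (at least 2; at least
#'   `2 * team_size` for team games).
#' @param games_total Number of games to simulate.
#' @param seed Master seed; every stage derives its RNG stream from it
#'   (population uses `seed`, match simulation `seed + 1`).
#' @param beta Performance noise deviation, tsp.
#' @param intercept Baseline log10 skill after the first game (I0).
#' @param alpha Learning exponent of the law of practice.
#' @param effect_loyal,effect_tob,effect_faith Main behaviour effects
#'   on log10 skill.
#' @param effect_exp_loyal,effect_exp_tob,effect_exp_faith Interaction
#'   of each behaviour covariate with log10 experience.
#' @param player_sd SD of the per-player random intercept (log10
#'   scale).
#' @param tob_shape,loyalty_shape `c(shape1, shape2)` of the Beta
#'   distributions the behavioural targets are drawn from.
#' @param team_size Members per team in team games (default 2, i.e.
#'   2v2); solo games are always 1v1.
#' @param entry_fraction Players enter the world at positions drawn
#'   uniformly over the first `entry_fraction` of the stream (a small
#'   seed group is present from the start); 0 makes the whole
#'   population present from game one.
#' @param career_fraction Mean career length as a fraction of the
#'   stream: each player stays active for an exponentially distributed
#'   span with mean `career_fraction * games_total` (censored by the
#'   end of the stream), `Inf` for no exit. Continuous arrivals plus
#'   finite careers keep the opponent pool's experience composition
#'   stationary, as on a long-running game server, and produce the
#'   heavy-tailed activity totals real populations show.
#' @param games_budget Optional cap on games per player; finite budgets
#'   use a sequential simulator and may truncate the stream.
#' @param churn_hazard Optional retirement model (an extra, off by
#'   default): after their k-th lost game a player retires with
#'   probability `min(1, churn_hazard * k)`.
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_players = 2000,
                              games_total = 100000,
                              seed = 1,
                              beta = 25 / 6,
                              intercept = 1.415,
                              alpha = 0.016,
                              effect_loyal = 0.0038,
                              effect_tob = -0.0469,
                              effect_faith = 0.1067,
                              effect_exp_loyal = 0.004,
                              effect_exp_tob = 0.016,
                              effect_exp_faith = -0.026,
                              player_sd = sqrt(0.002),
                              tob_shape = c(1.2, 1.8),
                              loyalty_shape = c(1.5, 1.5),
                              team_size = 2,
                              entry_fraction = 0.9,
                              career_fraction = 0.15,
                              games_budget = Inf,
                              churn_hazard = 0) {
  stopifnot(n_players >= 2, games_total >= 1, beta > 0, alpha >= 0,
            player_sd >= 0, team_size >= 2, games_budget >= 1,
            churn_hazard >= 0, length(tob_shape) == 2,
            length(loyalty_shape) == 2, all(tob_shape > 0),
            all(loyalty_shape > 0), entry_fraction >= 0, entry_fraction < 1,
            career_fraction > 0)
  structure(list(
    n_players = as.integer(n_players), games_total = as.integer(games_total),
    seed = as.integer(seed), beta = beta, intercept = intercept,
    alpha = alpha, effect_loyal = effect_loyal, effect_tob = effect_tob,
    effect_faith = effect_faith, effect_exp_loyal = effect_exp_loyal,
    effect_exp_tob = effect_exp_tob, effect_exp_faith = effect_exp_faith,
    player_sd = player_sd, tob_shape = tob_shape,
    loyalty_shape = loyalty_shape, team_size = as.integer(team_size),
    entry_fraction = entry_fraction, career_fraction = career_fraction,
    games_budget = games_budget, churn_hazard = churn_hazard
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d players, %d games, seed %d, beta %.3f\n",
              x$n_players, x$games_total, x$seed, x$beta))
  cat(sprintf("  growth: log10 skill = %.3f + %.3f log10(n) (+ effects)\n",
              x$intercept, x$alpha))
  cat(sprintf("  effects (log10): loyal %+.3f, tob %+.3f, loyal:tob %+.3f\n",
              x$effect_loyal, x$effect_tob, x$effect_faith))
  cat(sprintf("           x log10(n): %+.3f, %+.3f, %+.3f; player SD %.4f\n",
              x$effect_exp_loyal, x$effect_exp_tob, x$effect_exp_faith,
              x$player_sd))
  invisible(x)
}

#' Generate a synthetic player population
#'
#' Draws each player's random intercept and behavioural targets, and
#' assigns preferred partners by random matching. Preference is mutual
#' (matched pairs prefer each other) and the two members of a pair
#' share the same behavioural targets, so that each player's realized
#' TOB and loyalty can converge to their own targets (with an odd
#' population size the leftover player's preference is one-sided).
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `player_id, u, tob_target,
#'   loyalty_target, preferred_partner, entry, exit` (the last two are
#'   the stream positions between which the player is active).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_players
  if (n < 2) stop("cannot form games with fewer than 2 players")
  withr::with_seed(config$seed, {
    ids <- sprintf("p%05d", seq_len(n))
    u <- stats::rnorm(n, 0, config$player_sd)
    perm <- sample.int(n)
    n_pair <- n %/% 2
    first <- perm[seq_len(n_pair)]
    second <- perm[n_pair + seq_len(n_pair)]
    tob_pair <- stats::rbeta(n_pair, config$tob_shape[1], config$tob_shape[2])
    loy_pair <- stats::rbeta(n_pair, config$loyalty_shape[1],
                             config$loyalty_shape[2])
    tob <- numeric(n)
    loy <- numeric(n)
    pref <- integer(n)
    tob[first] <- tob_pair; tob[second] <- tob_pair
    loy[first] <- loy_pair; loy[second] <- loy_pair
    pref[first] <- second; pref[second] <- first
    if (n %% 2 == 1) {
      odd <- perm[n]
      tob[odd] <- stats::rbeta(1, config$tob_shape[1], config$tob_shape[2])
      loy[odd] <- stats::rbeta(1, config$loyalty_shape[1],
                               config$loyalty_shape[2])
      pref[odd] <- sample(seq_len(n)[-odd], 1)
    }
    # demographics: a seed group present from game 0, the rest arriving
    # uniformly over the entry window, with exponential career lengths.
    # Preferred pairs are contemporaries: both members share the pair's
    # entry and career window (partners recruit each other), otherwise
    # the loyalty channel would be severed by non-overlapping careers.
    G <- config$games_total
    m0 <- min(n, max(2L * config$team_size, ceiling(0.02 * n)))
    n_seed_pairs <- ceiling(m0 / 2)
    pair_order <- sample.int(n_pair)
    pair_entry <- numeric(n_pair)
    if (n_pair > n_seed_pairs && config$entry_fraction > 0) {
      late <- pair_order[(n_seed_pairs + 1):n_pair]
      pair_entry[late] <- floor(stats::runif(length(late), 0,
                                             config$entry_fraction * G))
    }
    pair_exit <- if (is.finite(config$career_fraction)) {
      pair_entry + stats::rexp(n_pair, 1 / (config$career_fraction * G))
    } else {
      rep(Inf, n_pair)
    }
    entry <- numeric(n)
    exit <- rep(Inf, n)
    entry[first] <- pair_entry; entry[second] <- pair_entry
    exit[first] <- pair_exit; exit[second] <- pair_exit
    if (n %% 2 == 1) {
      odd <- perm[n]
      entry[odd] <- if (config$entry_fraction > 0) {
        floor(stats::runif(1, 0, config$entry_fraction * G))
      } else 0
      exit[odd] <- if (is.finite(config$career_fraction)) {
        entry[odd] + stats::rexp(1, 1 / (config$career_fraction * G))
      } else Inf
    }
    tibble::tibble(player_id = ids, u = u, tob_target = tob,
                   loyalty_target = loy, preferred_partner = ids[pref],
                   entry = entry, exit = exit)
  })
}

#' True latent skill at a given experience
#'
#' The generative skill law on the log10 scale:
#' `log10 S = I0 + u + c_l * loyalty + c_t * tob + c_lt * loyalty*tob +
#' (alpha + c_el * loyalty + c_et * tob + c_elt * loyalty*tob) *
#' log10(n)`. With all effects and `u` zero this reduces to the plain
#' law of practice `S = 10^I0 * n^alpha`.
#'
#' @param population A population tibble (rows recycled against
#'   `experience`).
#' @param experience Experience index n (>= 1), vectorized.
#' @param config A [simulation_config()].
#' @return Numeric vector of true skills, tsp (strictly positive).
#' @export
true_skill_at <- function(population, experience, config) {
  stopifnot(all(experience >= 1))
  l <- population$loyalty_target
  t <- population$tob_target
  lt <- l * t
  logn <- log10(experience)
  log_s <- config$intercept + population$u +
    config$effect_loyal * l + config$effect_tob * t +
    config$effect_faith * lt +
    (config$alpha + config$effect_exp_loyal * l +
       config$effect_exp_tob * t + config$effect_exp_faith * lt) * logn
  10^log_s
}

# Internal team-initiation propensity. A player's realized games are a
# mix of self-initiated games and drafted slots; with drafting weights
# q (opposing team leader), q(1-loyalty) (random partner) and 1-q (solo
# opponent), a player who initiates team games with probability
# q = tob/(2 - tob) realizes a team-game fraction of
# 2q/(1+q) = tob in expectation.
initiation_prob <- function(tob_target) {
  ifelse(tob_target >= 1, 1, tob_target / (2 - tob_target))
}

# Weighted draws with per-row exclusion sets, resampling collisions.
# `exclude` is a matrix (rows = draws) of forbidden player indices;
# `fallback` replaces degenerate weights (all mass excluded / zero).
draw_excluding <- function(n_draw, weights, exclude, fallback = NULL) {
  if (n_draw == 0) return(integer(0))
  if (is.null(fallback)) fallback <- rep(1, length(weights))
  w <- if (sum(weights) > 0) weights else fallback
  out <- sample.int(length(w), n_draw, replace = TRUE, prob = w)
  tries <- 0L
  repeat {
    bad <- rowSums(exclude == out) > 0
    if (!any(bad)) break
    tries <- tries + 1L
    if (tries > 50L) w <- fallback  # excluded players hold all the mass
    out[bad] <- sample.int(length(w), sum(bad), replace = TRUE, prob = w)
  }
  out
}

#' Simulate a chronological game history
#'
#' Per game: an initiator is drawn uniformly; with probability
#' `q = tob/(2 - tob)` they start a team game, otherwise a 1v1 against
#' an opponent drawn with weight `1 - q`. Each team is formed leader
#' first; the leader's first teammate is their preferred partner with
#' probability equal to their loyalty target, otherwise (and for any
#' further slots) a player drawn with weight `q * (1 - loyalty)`. The
#' opposing leader is drawn with weight `q`. Every participant then
#' exhibits a performance `Normal(true skill at current experience,
#' beta^2)`; the team with the larger summed performance wins (exact
#' ties are resampled). With the default infinite games budget and no
#' churn the simulation is fully vectorized; finite budgets or a
#' nonzero churn hazard switch to a sequential simulator that truncates
#' the stream (with a warning) when fewer than two players remain
#' available.
#'
#' @param population A population tibble from [generate_population()].
#' @param config The same [simulation_config()].
#' @return A validated game-history tibble (see [read_games()]) with a
#'   `truth` attribute: one row per game (`seq, n_participants,
#'   delta_true, winner_first`) giving the team-1-minus-team-2
#'   true-skill difference at the time of the game and whether team 1
#'   won, for calibration checks.
#' @export
simulate_history <- function(population, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- nrow(population)
  k <- config$team_size
  q <- initiation_prob(population$tob_target)
  if (any(q > 0) && n < 2 * k) {
    stop("population size must be at least ", 2 * k, " for team games")
  }
  if (is.finite(config$games_budget) || config$churn_hazard > 0) {
    return(simulate_history_sequential(population, config))
  }
  withr::with_seed(config$seed + 1L, {
    G <- config$games_total
    loy <- population$loyalty_target
    pref <- match(population$preferred_partner, population$player_id)
    w_partner_all <- q * (1 - loy)
    w_solo_all <- 1 - q
    entry <- if ("entry" %in% names(population)) population$entry else
      numeric(n)
    exit <- if ("exit" %in% names(population)) population$exit else
      rep(Inf, n)
    n_chunk <- min(256L, G)
    bounds <- unique(round(seq(0, G, length.out = n_chunk + 1)))
    is_team <- logical(G)
    team_rows <- vector("list", length(bounds) - 1)
    solo_rows <- vector("list", length(bounds) - 1)
    for (ci in seq_len(length(bounds) - 1)) {
      g0 <- bounds[ci]
      nb <- bounds[ci + 1] - g0
      active <- as.numeric(entry <= g0 & exit > g0)
      if (sum(active) < 2 * k) active <- as.numeric(entry <= g0)
      w_partner <- w_partner_all * active
      w_leader <- q * active
      w_solo <- w_solo_all * active
      init <- sample.int(n, nb, replace = TRUE, prob = active)
      team_b <- stats::runif(nb) < q[init]
      is_team[g0 + seq_len(nb)] <- team_b
      tg <- which(team_b)
      sg <- which(!team_b)
      if (length(tg) > 0) {
        m <- matrix(NA_integer_, length(tg), 2 * k)
        m[, 1] <- init[tg]
        # side A: the first extra slot is the preferred partner
        use_pref <- stats::runif(length(tg)) < loy[m[, 1]]
        cand <- ifelse(use_pref & pref[m[, 1]] != m[, 1] &
                         active[pref[m[, 1]]] > 0, pref[m[, 1]], NA)
        m[, 2] <- cand
        nas <- which(is.na(m[, 2]))
        m[nas, 2] <- draw_excluding(length(nas), w_partner,
                                    m[nas, 1, drop = FALSE], active)
        if (k > 2) {
          for (j in 3:k) {
            m[, j] <- draw_excluding(length(tg), w_partner,
                                     m[, seq_len(j - 1), drop = FALSE], active)
          }
        }
        # side B: leader, then the leader's preferred partner / fills
        m[, k + 1] <- draw_excluding(length(tg), w_leader,
                                     m[, seq_len(k), drop = FALSE], active)
        lead_b <- m[, k + 1]
        use_pref_b <- stats::runif(length(tg)) < loy[lead_b]
        cand <- ifelse(use_pref_b & active[pref[lead_b]] > 0,
                       pref[lead_b], NA)
        cand[!is.na(cand) &
               rowSums(m[, seq_len(k + 1), drop = FALSE] == cand,
                       na.rm = TRUE) > 0] <- NA
        m[, k + 2] <- cand
        nas <- which(is.na(m[, k + 2]))
        m[nas, k + 2] <- draw_excluding(length(nas), w_partner,
                                        m[nas, seq_len(k + 1), drop = FALSE],
                                        active)
        if (k > 2) {
          for (j in (k + 3):(2 * k)) {
            m[, j] <- draw_excluding(length(tg), w_partner,
                                     m[, seq_len(j - 1), drop = FALSE], active)
          }
        }
        team_rows[[ci]] <- m
      }
      if (length(sg) > 0) {
        s <- matrix(NA_integer_, length(sg), 2)
        s[, 1] <- init[sg]
        s[, 2] <- draw_excluding(length(sg), w_solo, s[, 1, drop = FALSE],
                                 active)
        solo_rows[[ci]] <- s
      }
    }
    part_team <- do.call(rbind, team_rows)
    part_solo <- do.call(rbind, solo_rows)
    tg <- which(is_team)
    sg <- which(!is_team)
    # long participant table in (game, team, slot) order
    n_part <- ifelse(is_team, 2L * k, 2L)
    game_of <- rep.int(seq_len(G), n_part)
    player <- integer(sum(n_part))
    team <- integer(sum(n_part))
    if (length(tg) > 0) {
      rows_t <- which(is_team[game_of])
      player[rows_t] <- as.vector(t(part_team))
      team[rows_t] <- rep_len(rep(1:2, each = k), length(rows_t))
    }
    if (length(sg) > 0) {
      rows_s <- which(!is_team[game_of])
      player[rows_s] <- as.vector(t(part_solo))
      team[rows_s] <- rep_len(1:2, length(rows_s))
    }
    # running experience per player, in stream order
    pf <- factor(player, levels = seq_len(n))
    ord <- order(pf, seq_along(player))
    experience <- integer(length(player))
    experience[ord] <- sequence(tabulate(pf, nbins = n))
    skill <- true_skill_at(population[player, ], experience, config)
    perf <- stats::rnorm(length(player), skill, config$beta)
    side <- (game_of - 1L) * 2L + team
    sums <- rowsum(perf, side)[, 1]
    s1 <- sums[seq(1, 2 * G, by = 2)]
    s2 <- sums[seq(2, 2 * G, by = 2)]
    while (any(tied <- s1 == s2)) {
      redo <- which(game_of %in% which(tied))
      perf[redo] <- stats::rnorm(length(redo), skill[redo], config$beta)
      sums <- rowsum(perf, side)[, 1]
      s1 <- sums[seq(1, 2 * G, by = 2)]
      s2 <- sums[seq(2, 2 * G, by = 2)]
    }
    winner <- ifelse(s1 > s2, 1L, 2L)
    skill_sums <- rowsum(skill, side)[, 1]
    delta_true <- skill_sums[seq(1, 2 * G, by = 2)] -
      skill_sums[seq(2, 2 * G, by = 2)]
    # assemble the canonical game tibble
    ids <- population$player_id[player]
    team_key <- factor(side, levels = unique(side[order(game_of, team)]))
    team_members <- split(ids, team_key)
    teams <- unname(split(team_members, rep(seq_len(G), each = 2)))
    teams <- lapply(teams, unname)
    outcome <- rep(list(c(1L, 2L)), G)
    outcome[winner == 2L] <- list(c(2L, 1L))
    games <- new_games(sprintf("g%07d", seq_len(G)), seq_len(G) - 1L,
                       teams, outcome)
    attr(games, "truth") <- tibble::tibble(
      seq = games$seq,
      n_participants = n_part,
      delta_true = delta_true,
      winner_first = winner == 1L
    )
    games
  })
}

# Sequential simulator: honours finite per-player games budgets and the
# optional churn model. Slower; intended for small worlds.
simulate_history_sequential <- function(population, config) {
  withr::with_seed(config$seed + 1L, {
    n <- nrow(population)
    k <- config$team_size
    q <- initiation_prob(population$tob_target)
    loy <- population$loyalty_target
    pref <- match(population$preferred_partner, population$player_id)
    w_partner <- q * (1 - loy)
    w_solo <- 1 - q
    entry <- if ("entry" %in% names(population)) population$entry else
      numeric(n)
    exit <- if ("exit" %in% names(population)) population$exit else
      rep(Inf, n)
    count <- integer(n)
    losses <- integer(n)
    alive <- rep(TRUE, n)
    res_teams <- vector("list", config$games_total)
    res_outcome <- vector("list", config$games_total)
    truth <- matrix(NA_real_, config$games_total, 3)
    g <- 0L
    pick <- function(pool, w) {
      if (length(pool) == 0) return(NA_integer_)
      if (length(pool) == 1) return(pool)
      wt <- w[pool]
      if (sum(wt) <= 0) wt <- rep(1, length(pool))
      pool[sample.int(length(pool), 1, prob = wt)]
    }
    while (g < config$games_total) {
      open <- which(alive & count < config$games_budget & entry <= g &
                      exit > g)
      if (length(open) < 2) {
        open <- which(alive & count < config$games_budget & entry <= g)
      }
      if (length(open) < 2) {
        warning("games budget exhausted after ", g, " of ",
                config$games_total, " games; stream truncated")
        break
      }
      i <- open[sample.int(length(open), 1)]
      others <- setdiff(open, i)
      team_game <- stats::runif(1) < q[i] && length(others) >= 2 * k - 1
      if (team_game) {
        side_a <- i
        if (alive[pref[i]] && count[pref[i]] < config$games_budget &&
            pref[i] %in% open && stats::runif(1) < loy[i] && pref[i] != i) {
          side_a <- c(side_a, pref[i])
        }
        while (length(side_a) < k) {
          side_a <- c(side_a, pick(setdiff(others, side_a), w_partner))
        }
        lead_b <- pick(setdiff(others, side_a), q)
        side_b <- lead_b
        pb <- pref[lead_b]
        if (!is.na(pb) && alive[pb] && pb %in% open &&
            !(pb %in% c(side_a, side_b)) && stats::runif(1) < loy[lead_b]) {
          side_b <- c(side_b, pb)
        }
        while (length(side_b) < k) {
          side_b <- c(side_b, pick(setdiff(others, c(side_a, side_b)),
                                   w_partner))
        }
        teams_idx <- list(side_a, side_b)
      } else {
        j <- pick(others, w_solo)
        teams_idx <- list(i, j)
      }
      g <- g + 1L
      flat <- unlist(teams_idx)
      count[flat] <- count[flat] + 1L
      skill <- true_skill_at(population[flat, ], count[flat], config)
      sizes <- lengths(teams_idx)
      grp <- rep(seq_along(teams_idx), sizes)
      repeat {
        perf <- rowsum(stats::rnorm(length(flat), skill, config$beta), grp)[, 1]
        if (perf[1] != perf[2]) break
      }
      win1 <- perf[1] > perf[2]
      res_teams[[g]] <- lapply(teams_idx, function(ti) population$player_id[ti])
      res_outcome[[g]] <- if (win1) c(1L, 2L) else c(2L, 1L)
      truth[g, ] <- c(length(flat),
                      sum(skill[grp == 1]) - sum(skill[grp == 2]), win1)
      losers <- teams_idx[[if (win1) 2 else 1]]
      losses[losers] <- losses[losers] + 1L
      if (config$churn_hazard > 0) {
        churn <- stats::runif(length(losers)) <
          pmin(1, config$churn_hazard * losses[losers])
        alive[losers[churn]] <- FALSE
      }
    }
    res_teams <- res_teams[seq_len(g)]
    res_outcome <- res_outcome[seq_len(g)]
    games <- new_games(sprintf("g%07d", seq_len(g)), seq_len(g) - 1L,
                       res_teams, res_outcome)
    attr(games, "truth") <- tibble::tibble(
      seq = games$seq,
      n_participants = as.integer(truth[seq_len(g), 1]),
      delta_true = truth[seq_len(g), 2],
      winner_first = truth[seq_len(g), 3] == 1
    )
    games
  })
}

#' Simulate a population and its game history in one call
#'
#' @param config A [simulation_config()].
#' @return A list with elements `population` and `games` (the latter
#'   carrying the `truth` attribute of [simulate_history()]).
#' @export
simulate_games <- function(config) {
  population <- generate_population(config)
  list(population = population,
       games = simulate_history(population, config))
}

#' Write / read the per-player truth table
#'
#' Writes the population's true parameters plus an echo of every scalar
#' configuration value (including the seed and all injected
#' coefficients) as a commented CSV, so that parameter-recovery tests
#' can reload exactly what generated a stream.
#'
#' @param population A population tibble.
#' @param config The generating [simulation_config()].
#' @param path Output path.
#' @return `path` invisibly (`write_truth`); a population tibble with a
#'   `config` attribute of parsed scalars (`read_truth`).
#' @export
write_truth <- function(population, config, path) {
  scalars <- config[vapply(config, function(x) is.numeric(x) &&
                             length(x) == 1, logical(1))]
  header <- sprintf("# %s: %s", names(scalars),
                    vapply(scalars, format, character(1), digits = 17))
  out <- population
  for (nm in c("intercept", "alpha", "effect_loyal", "effect_tob",
               "effect_faith", "effect_exp_loyal", "effect_exp_tob",
               "effect_exp_faith", "beta", "player_sd")) {
    out[[nm]] <- config[[nm]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  kv <- sub("^# ", "", lines[hdr])
  cfg <- as.list(as.numeric(sub("^[^:]+: ", "", kv)))
  names(cfg) <- sub(":.*$", "", kv)
  df <- utils::read.csv(text = lines[-hdr], stringsAsFactors = FALSE,
                        colClasses = c(player_id = "character",
                                       preferred_partner = "character"))
  out <- tibble::as_tibble(df)
  attr(out, "config") <- cfg
  out
}
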