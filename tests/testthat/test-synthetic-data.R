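test_that("the generator is deterministic given its seed", {
  cfg <- small_config(seed = 9)
  a <- simulate_games(cfg)
  b <- simulate_games(cfg)
  expect_identical(a$population, b$population)
  expect_identical(a$games, b$games)
  other <- simulate_games(small_config(seed = 10))
  expect_false(identical(a$games$outcome, other$games$outcome))
})

test_that("population structure follows the configuration", {
  cfg <- small_config(seed = 2)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), cfg$n_players)
  expect_false(any(pop$preferred_partner == pop$player_id))
  # preference is mutual with shared targets and shared careers
  m <- match(pop$preferred_partner, pop$player_id)
  mutual <- pop$preferred_partner[m] == pop$player_id
  expect_gte(sum(mutual), cfg$n_players - 1)
  expect_equal(pop$tob_target[mutual], pop$tob_target[m][mutual])
  expect_equal(pop$entry[mutual], pop$entry[m][mutual])
  expect_true(all(pop$exit > pop$entry))
  expect_error(generate_population(simulation_config(n_players = 1)),
               "n_players")
})

test_that("true skill reduces to the plain law of practice", {
  cfg <- small_config(effect_loyal = 0, effect_tob = 0, effect_faith = 0,
                      effect_exp_loyal = 0, effect_exp_tob = 0,
                      effect_exp_faith = 0, player_sd = 0)
  pop <- generate_population(cfg)
  n <- c(1, 10, 100)
  s <- true_skill_at(pop[rep(1, 3), ], n, cfg)
  expect_equal(s, 10^cfg$intercept * n^cfg$alpha, tolerance = 1e-12)
  # at n = 1 the exponent is irrelevant
  cfg2 <- small_config(alpha = 0.5, player_sd = 0, effect_loyal = 0,
                       effect_tob = 0, effect_faith = 0,
                       effect_exp_loyal = 0, effect_exp_tob = 0,
                       effect_exp_faith = 0)
  expect_equal(true_skill_at(pop[1, ], 1, cfg2), 10^cfg2$intercept)
  # higher faithfulness -> higher true skill at every n when c_lt > 0
  p2 <- pop[c(1, 1), ]
  p2$u <- 0
  p2$loyalty_target <- c(0.2, 0.9)
  p2$tob_target <- c(0.9, 0.9)
  cfg3 <- small_config(effect_loyal = 0, effect_tob = 0, effect_faith = 0.1,
                       effect_exp_loyal = 0, effect_exp_tob = 0,
                       effect_exp_faith = 0)
  for (n in c(1, 10, 400)) {
    s <- true_skill_at(p2, n, cfg3)
    expect_gt(s[2], s[1])
  }
})

test_that("degenerate behaviour targets shape the stream", {
  cfg <- small_config(seed = 5)
  pop <- generate_population(cfg)
  pop$tob_target <- 0
  games <- simulate_history(pop, cfg)
  expect_true(all(vapply(games$teams, function(ts) max(lengths(ts)),
                         numeric(1)) == 1))
  # loyalty 1: every team game is played with the preferred partner
  pop2 <- generate_population(cfg)
  pop2$loyalty_target <- 1
  games2 <- simulate_history(pop2, cfg)
  prof <- behavior_profiles(build_histories(games2))
  with_teams <- prof[prof$team_games > 0, ]
  expect_gt(nrow(with_teams), 5)
  expect_true(all(with_teams$loyalty == 1))
})

test_that("realized behaviour converges to its targets without bias", {
  # large enough that the active pool makes accidental draws of the
  # preferred partner negligible (the convergence claim is asymptotic)
  cfg <- simulation_config(n_players = 400, games_total = 80000, seed = 7)
  sim <- simulate_games(cfg)
  prof <- behavior_profiles(build_histories(sim$games))
  m <- match(prof$player_id, sim$population$player_id)
  act <- prof$games_played >= 200
  expect_gt(sum(act), 100)
  dev_tob <- prof$tob[act] - sim$population$tob_target[m][act]
  expect_lt(abs(mean(dev_tob)), 0.02)        # no systematic bias
  expect_lt(mean(abs(dev_tob)), 0.05)        # LLN-scale agreement
  okl <- act & !is.na(prof$loyalty) & prof$team_games >= 100
  dev_loy <- prof$loyalty[okl] - sim$population$loyalty_target[m][okl]
  expect_lt(abs(mean(dev_loy)), 0.02)
  expect_lt(mean(abs(dev_loy)), 0.05)
})

test_that("finite budgets truncate the stream with a warning", {
  cfg <- small_config(n_players = 10, games_total = 500, games_budget = 20,
                      entry_fraction = 0, career_fraction = Inf)
  pop <- generate_population(cfg)
  expect_warning(games <- simulate_history(pop, cfg), "truncated")
  expect_lt(nrow(games), 500)
  h <- build_histories(games)
  expect_true(all(tapply(h$experience, h$player_id, max) <= 20))
})

test_that("the optional churn hazard retires losing players", {
  cfg <- small_config(n_players = 30, games_total = 400, churn_hazard = 0.05,
                      entry_fraction = 0, career_fraction = Inf)
  pop <- generate_population(cfg)
  games <- tryCatch(simulate_history(pop, cfg), warning = function(w) {
    suppressWarnings(simulate_history(pop, cfg))
  })
  expect_true(nrow(games) >= 1)
  validate_games(games)
  h <- build_histories(games)
  totals <- tapply(h$experience, h$player_id, max)
  expect_gt(stats::sd(totals), 0)  # churn spreads total activity
})

test_that("truth tables round-trip with their configuration echo", {
  cfg <- small_config(seed = 8)
  pop <- generate_population(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(pop, cfg, path)
  back <- read_truth(path)
  expect_equal(back$u, pop$u)
  expect_equal(back$tob_target, pop$tob_target)
  expect_equal(back$loyalty_target, pop$loyalty_target)
  expect_identical(back$preferred_partner, pop$preferred_partner)
  cfg_echo <- attr(back, "config")
  expect_equal(cfg_echo$seed, cfg$seed)
  expect_equal(cfg_echo$beta, cfg$beta)
  # every injected coefficient is also a column
  for (nm in c("intercept", "alpha", "effect_loyal", "effect_tob",
               "effect_faith", "effect_exp_loyal", "effect_exp_tob",
               "effect_exp_faith")) {
    expect_equal(unique(back[[nm]]), cfg[[nm]])
  }
})

test_that("team outcomes follow the additive performance model", {
  # deterministic-skill world: outcome frequencies must match the
  # closed-form Gaussian win probability per true-delta bin
  cfg <- simulation_config(n_players = 300, games_total = 8000, seed = 31)
  sim <- simulate_games(cfg)
  tr <- attr(sim$games, "truth")
  p1 <- pnorm(tr$delta_true / sqrt(tr$n_participants * cfg$beta^2))
  bins <- cut(p1, quantile(p1, 0:5 / 5), include.lowest = TRUE)
  obs <- tapply(tr$winner_first, bins, mean)
  pred <- tapply(p1, bins, mean)
  n <- tapply(p1, bins, length)
  z <- (obs - pred) / sqrt(pred * (1 - pred) / n)
  expect_true(all(abs(z) < 3))
})
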