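default_beta <- 25 / 6

test_that("team performance is additive in means and variances", {
  one <- team_performance(rating(25, 25 / 3))
  expect_equal(one$mean, 25)
  expect_equal(one$variance, 625 / 36 + 625 / 9)
  two <- team_performance(rating(c(25, 25), 25 / 3))
  expect_equal(two$mean, 50)
  expect_equal(two$variance, 2 * one$variance)
  sure <- team_performance(rating(c(30, 20), 0))
  expect_equal(sure$variance, 2 * default_beta^2)
  expect_error(team_performance(rating()[0, ]), "at least one")
})

test_that("difference summary is antisymmetric and rejects shared players", {
  a <- rating(25, 8.33)
  b <- rating(20, 8.33)
  d <- difference_summary(a, b)
  expect_equal(d$delta, 5)
  expect_equal(d$theta, 2 * default_beta^2 + 2 * 8.33^2)
  rev <- difference_summary(b, a)
  expect_equal(rev$delta, -d$delta)
  expect_equal(rev$theta, d$theta)
  balanced <- difference_summary(rating(c(30, 20), 5), rating(c(25, 25), 5))
  expect_equal(balanced$delta, 0)
  expect_error(
    difference_summary(rating(25, 5, player_id = "p1"),
                       rating(c(20, 22), 5, player_id = c("p1", "p2"))),
    "both teams")
})

test_that("win probability matches the Gaussian closed form", {
  expect_equal(win_probability(rating(25), rating(25)), 0.5)
  # oracle: normal CDF of delta / sqrt(theta)
  theta <- 2 * default_beta^2 + 2 * 8.33^2
  expect_equal(win_probability(rating(25, 8.33), rating(20, 8.33)),
               pnorm(5 / sqrt(theta)), tolerance = 1e-12)
  expect_equal(round(pnorm(5 / sqrt(theta)), 3), 0.648)
  expect_equal(win_probability(rating(25 + 1e6, 8.33), rating(25, 8.33)), 1,
               tolerance = 1e-12)
})

test_that("complements sum to one and teammate redistribution is irrelevant", {
  withr::with_seed(42, {
    for (i in 1:25) {
      a <- rating(runif(2, 10, 40), runif(2, 1, 10))
      b <- rating(runif(2, 10, 40), runif(2, 1, 10))
      expect_equal(win_probability(a, b) + win_probability(b, a), 1,
                   tolerance = 1e-12)
      # move mean skill between teammates, sigmas fixed
      shift <- runif(1, -5, 5)
      a2 <- a
      a2$mu <- a$mu + c(shift, -shift)
      expect_equal(win_probability(a2, b), win_probability(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact posterior moments match frozen quadrature values", {
  sigma0 <- 25 / 3
  theta <- 2 * default_beta^2 + 2 * sigma0^2
  won <- exact_posterior_moments(25, sigma0, 0 - 25, theta - sigma0^2, TRUE)
  # frozen from an independent scipy quadrature (cross-checked by
  # rejection sampling): mean 29.2052208700336, sd 7.1944813488311
  expect_equal(won$mean, 29.2052208700336, tolerance = 1e-9)
  expect_equal(sqrt(won$variance), 7.1944813488311, tolerance = 1e-9)
  lost <- exact_posterior_moments(25, sigma0, 0 + 25, theta - sigma0^2, FALSE)
  # mirror symmetry of the winning and losing cases about the prior mean
  expect_equal(lost$mean - 25, -(won$mean - 25), tolerance = 1e-9)
  expect_equal(lost$variance, won$variance, tolerance = 1e-9)
  expect_gt(won$mean, 25)  # winning is good news
  expect_lt(sqrt(won$variance), sigma0)
})

test_that("moment matching agrees with the quadrature oracle on a grid", {
  for (t in c(-3, 0, 3)) {
    for (ratio in c(0.2, 0.5, 0.8)) {
      cc <- 13
      sigma <- ratio * cc
      var_rest <- cc^2 - sigma^2
      mu <- 25
      delta <- t * cc
      ex <- exact_posterior_moments(mu, sigma, delta - mu, var_rest, TRUE)
      v <- dnorm(t) / pnorm(t)
      w <- v * (v + t)
      expect_equal(ex$mean, mu + sigma^2 / cc * v, tolerance = 1e-6)
      expect_equal(sqrt(ex$variance),
                   sigma * sqrt(1 - sigma^2 / cc^2 * w), tolerance = 1e-6)
    }
  }
})

test_that("two-team update moves winners up, losers down, shrinks sigma", {
  up <- moment_matched_update(rating(25), rating(25))
  expect_equal(up$winners$mu, 29.2052208700336, tolerance = 1e-6)
  expect_equal(up$winners$sigma, 7.1944813488311, tolerance = 1e-6)
  expect_equal(up$losers$mu, 25 - (up$winners$mu - 25), tolerance = 1e-12)
  # upset produces a larger surprise than the expected result
  upset <- moment_matched_update(rating(20, 5), rating(30, 5))
  expected <- moment_matched_update(rating(30, 5), rating(20, 5))
  expect_gt(abs(upset$winners$mu - 20), abs(expected$winners$mu - 30))
  # sigma strictly decreases for every participant
  withr::with_seed(7, {
    for (i in 1:20) {
      w <- rating(runif(2, 0, 50), runif(2, 0.5, 9))
      l <- rating(runif(2, 0, 50), runif(2, 0.5, 9))
      up <- moment_matched_update(w, l)
      expect_true(all(up$winners$sigma < w$sigma))
      expect_true(all(up$losers$sigma < l$sigma))
      expect_true(all(up$winners$mu >= w$mu))
      expect_true(all(up$losers$mu <= l$mu))
    }
  })
  expect_warning(moment_matched_update(rating(25, 0), rating(20, 0)),
                 "no-op")
})

test_that("tail-stable v keeps extreme updates finite and continuous", {
  v <- faithboost:::gauss_v
  # the tail branch agrees with the direct ratio where both are exact
  expect_equal(v(-5.001), dnorm(-5.001) / pnorm(-5.001), tolerance = 1e-9)
  expect_equal(v(-10), dnorm(-10) / pnorm(-10), tolerance = 1e-9)
  expect_true(is.finite(v(-40)))
  # far left tail: v(t) ~ -t + 1/(-t)
  expect_equal(v(-30), 30 + 1 / 30, tolerance = 1e-3)
  up <- moment_matched_update(rating(25, 2), rating(200, 2))
  expect_true(all(is.finite(c(up$winners$mu, up$winners$sigma))))
})

test_that("multi-team games reduce to sequential pairwise updates", {
  a <- rating(25, player_id = "a")
  b <- rating(25, player_id = "b")
  two <- multi_team_update(list(a, b), c(1, 2))
  direct <- moment_matched_update(a, b)
  expect_equal(two[[1]]$mu, direct$winners$mu)
  expect_equal(two[[2]]$sigma, direct$losers$sigma)
  # three-player free-for-all: first rises, last falls
  ffa <- multi_team_update(list(rating(25), rating(25), rating(25)),
                           c(2, 3, 1))
  expect_gt(ffa[[2]]$mu, 25)
  expect_lt(ffa[[1]]$mu, 25)
  # relabeling players does not change their updates
  perm <- multi_team_update(list(rating(25), rating(25), rating(25)),
                            c(3, 1, 2))
  expect_equal(perm[[3]]$mu, ffa[[2]]$mu)
  expect_equal(perm[[2]]$mu, ffa[[1]]$mu)
  expect_error(multi_team_update(list(rating(25), rating(25)), c(1, 1)),
               "permutation")
})

test_that("Elo expectations and updates follow the Gaussian model", {
  expect_equal(elo_win_probability(25, 25), 0.5)
  expect_equal(elo_win_probability(4, 0), pnorm(4 / (sqrt(2) * default_beta)))
  expect_equal(round(elo_win_probability(4, 0), 3), 0.751)
  expect_equal(elo_win_probability(1e9, 0), 1)
  expect_equal(elo_win_probability(4, 0) + elo_win_probability(0, 4), 1)
  up <- elo_update(25, 25, TRUE, K = 32)
  expect_equal(unname(up), c(41, 9))
  # heavy favourite winning gains almost nothing
  up <- elo_update(1000, 0, TRUE, K = 32)
  expect_lt(up[["si"]] - 1000, 1e-8)
  # an upset pays the full surprise; the pair update is zero-sum
  up <- elo_update(4, 0, FALSE, K = 32)
  expect_equal(up[["sj"]], 32 * pnorm(4 / (sqrt(2) * default_beta)),
               tolerance = 1e-12)
  expect_equal(sum(up), 4)
})

test_that("site points delta follows the capped ratio rule", {
  expect_equal(site_points_delta(2000, 1000), 10)
  expect_equal(site_points_delta(100, 10000), 100)
  expect_equal(site_points_delta(1500, 1500), 20)
  expect_error(site_points_delta(0, 10), "positive")
})

test_that("rate_history initializes, updates and records trajectories", {
  games <- game_tbl(list(list("a", "b")), 1L)
  traj <- rate_history(games)
  a <- traj[traj$player_id == "a", ]
  b <- traj[traj$player_id == "b", ]
  expect_gt(a$mu, 25)
  expect_lt(b$mu, 25)
  expect_lt(a$sigma, 25 / 3)
  expect_equal(a$experience, 1L)
  expect_false("c" %in% traj$player_id)
  empty <- rate_history(games[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("a winner streak gives a nondecreasing skill trajectory", {
  streak <- game_tbl(rep(list(list("w", "l")), 25), rep(1L, 25))
  traj <- rate_history(streak)
  w <- traj[traj$player_id == "w", ]
  expect_true(all(diff(w$mu) >= 0))
  expect_true(all(diff(w$sigma) < 0))
})

test_that("rate_history matches the frozen independent quadrature rater", {
  games <- read_games(test_path("fixtures", "diff_games.jsonl"), "jsonl")
  expected <- read.csv(test_path("fixtures", "diff_expected.csv"),
                       colClasses = c(player_id = "character"))
  traj <- rate_history(games)
  finals <- traj[!duplicated(traj$player_id, fromLast = TRUE), ]
  m <- match(expected$player_id, finals$player_id)
  expect_lt(max(abs(finals$mu[m] - expected$mu)), 1e-6)
  expect_lt(max(abs(finals$sigma[m] - expected$sigma)), 1e-6)
})
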