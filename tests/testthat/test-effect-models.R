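linear_world <- function(n = 400, b = c(28, 1, -1, 4), noise = 0, seed = 1) {
  withr::with_seed(seed, {
    loyalty <- runif(n)
    tob <- runif(n)
    skill <- b[1] + b[2] * loyalty + b[3] * tob + b[4] * loyalty * tob +
      rnorm(n, 0, noise)
  })
  data.frame(skill = skill, loyalty = loyalty, tob = tob,
             faithfulness = loyalty * tob)
}

test_that("cross-section tables apply the experience and eligibility gates", {
  # two players: one with 100 games, one with 99
  teams <- c(rep(list(list(c("a", "x"), c("b", "y"))), 99),
             list(list(c("a", "x"), c("c", "y"))))
  games <- game_tbl(teams, rep(1L, 100))
  h <- build_histories(games)
  traj <- rate_history(games)
  tab <- cross_section_table(h, traj, 100)
  expect_true("a" %in% tab$player_id)    # exactly 100 games
  expect_false("b" %in% tab$player_id)   # only 99
  mu100 <- traj$mu[traj$player_id == "a" & traj$experience == 100]
  expect_equal(tab$skill[tab$player_id == "a"], mu100)
  # covariates are the running values at the cutoff
  expect_equal(tab$tob[tab$player_id == "a"], 1)
  # nobody reaches experience 500: empty table, clean downstream error
  empty <- cross_section_table(h, traj, 500)
  expect_equal(nrow(empty), 0)
  expect_error(fit_cross_section(empty), "observations")
})

test_that("noiseless linear worlds are recovered exactly", {
  fit <- fit_cross_section(linear_world())
  expect_equal(fit$terms$estimate, c(28, 1, -1, 4), tolerance = 1e-8)
  dup <- linear_world()
  dup$faithfulness <- dup$tob
  expect_error(fit_cross_section(dup), "collinear")
})

test_that("pure-noise responses rarely reach |t| = 4", {
  bad <- 0
  for (s in 1:30) {
    tab <- linear_world(n = 500, b = c(0, 0, 0, 0), noise = 1, seed = s)
    fit <- fit_cross_section(tab)
    if (any(abs(fit$terms$t_value[-1]) >= 4)) bad <- bad + 1
  }
  expect_lte(bad, 1)
})

test_that("variance inflation follows 1 / (1 - R^2)", {
  # a full factorial design is exactly orthogonal
  d <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
  expect_equal(unname(variance_inflation(d)), rep(1, 3), tolerance = 1e-12)
  withr::with_seed(3, {
    x1 <- rnorm(500)
    near <- data.frame(x1 = x1, x2 = x1 + rnorm(500, 0, 0.01))
  })
  expect_true(all(variance_inflation(near) > 10))
  # bivariate normal with correlation 0.6: VIF -> 1 / (1 - 0.36)
  withr::with_seed(4, {
    z <- rnorm(10000)
    x <- z * 0.6 + rnorm(10000) * sqrt(1 - 0.36)
    biv <- data.frame(z = z, x = x)
  })
  expect_equal(unname(variance_inflation(biv)), rep(1.5625, 2),
               tolerance = 0.05)
})

test_that("variance inflation agrees with the car implementation", {
  skip_if_not_installed("car")
  tab <- linear_world(n = 300, noise = 1, seed = 9)
  ours <- variance_inflation(tab[, c("loyalty", "tob", "faithfulness")])
  fit <- lm(skill ~ loyalty + tob + faithfulness, data = tab)
  theirs <- car::vif(fit)
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-10)
})

test_that("the TOB reversal threshold is -beta_tob / beta_faith", {
  expect_equal(round(tob_reversal_threshold(-1.0042, 3.7077), 2), 0.27)
  expect_equal(tob_reversal_threshold(-1, 2), 0.5)
  expect_warning(thr <- tob_reversal_threshold(1, 2), "no reversal")
  expect_equal(thr, -0.5)
  # scale invariance
  expect_equal(tob_reversal_threshold(-1.0042 * 3, 3.7077 * 3),
               tob_reversal_threshold(-1.0042, 3.7077))
  expect_error(tob_reversal_threshold(-1, 0), "undefined")
  fit <- fit_cross_section(linear_world())
  expect_equal(tob_reversal_threshold(fit), 0.25, tolerance = 1e-6)
})

test_that("the mixed model reduces to OLS without player variance", {
  withr::with_seed(21, {
    d <- expand.grid(player = paste0("p", 1:40), experience = 10:60)
    d$loyalty <- runif(nrow(d))
    d$tob <- runif(nrow(d))
    d$skill <- 10^(1.4 + 0.02 * log10(d$experience) - 0.04 * d$tob +
                     0.09 * d$loyalty * d$tob + rnorm(nrow(d), 0, 0.02))
  })
  mf <- suppressWarnings(fit_mixed(d, experience_range = c(10, 60)))
  ols <- lm(log10(skill) ~ log10(experience) * loyalty * tob, data = d)
  expect_equal(mf$terms$estimate, unname(coef(ols)), tolerance = 1e-4)
  expect_equal(mf$n_groups, 40)
  const <- d
  const$tob <- 0.5
  expect_error(fit_mixed(const, experience_range = c(10, 60)), "constant")
})

test_that("normalized estimates match the printed transform and invert", {
  expect_equal(round(unname(normalize_estimates(1.415)), 2), 26)
  nm <- normalize_estimates(1.415, c(lt = 0.090))
  expect_equal(round(unname(nm["lt"]), 2), 5.99)
  expect_equal(unname(normalize_estimates(1.415, c(x = 0))["x"]), 0)
  # round trip: c = log10(norm + 10^I) - I
  est <- c(a = 0.016, b = -0.044, c = 0.090, d = -0.026)
  nm <- normalize_estimates(1.415, est)
  back <- log10(nm[-1] + 10^1.415) - 1.415
  expect_equal(unname(back), unname(est), tolerance = 1e-12)
})
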