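#' Behaviour-effect models
#'
#' Two models quantify how grouping behaviour modulates the skill
#' expected from experience. The cross-sectional model, at a fixed
#' experience E,
#' \deqn{skill_i \sim \beta_1 loyalty_i + \beta_2 TOB_i + \beta_3 faithfulness_i}
#' is fitted by ordinary least squares, with faithfulness the exact
#' elementwise product loyalty * TOB. The overall longitudinal model is
#' a linear mixed model on the log10 scale,
#' `log10(skill) ~ log10(experience) * loyalty * TOB + (1 | player)`,
#' fitted by REML; its estimates are back-transformed to TrueSkill
#' points via the normalized-estimate formula (see
#' [normalize_estimates()]).
#'
#' @name effect-models
#' @keywords internal
NULL

#' Cross-sectional table at a fixed experience
#'
#' One row per qualifying player: skill (the post-game posterior mean
#' after the player's game number `experience`) plus the behaviour
#' covariates. A player qualifies when they reached that experience and
#' are eligible (at least four team games under the chosen covariate
#' convention). Covariates are, by default, the running values at the
#' evaluated game; `"final"` uses whole-history values instead.
#'
#' @param histories A player-history table from [build_histories()].
#' @param trajectories A trajectory table from [rate_history()] on the
#'   same games.
#' @param experience The fixed experience E (e.g. 100).
#' @param covariates `"running"` (default) or `"final"`.
#' @return A tibble with columns `player_id, skill, loyalty, tob,
#'   faithfulness`.
#' @export
cross_section_table <- function(histories, trajectories, experience,
                                covariates = c("running", "final")) {
  covariates <- match.arg(covariates)
  stopifnot(experience >= 1)
  prof <- behavior_profiles(histories,
                            upto = if (covariates == "running") experience
                                   else NULL)
  at_e <- trajectories[trajectories$experience == experience, , drop = FALSE]
  # reaching a row at experience E implies >= E games played
  keep <- prof[prof$eligible & prof$player_id %in% at_e$player_id,
               , drop = FALSE]
  m <- match(keep$player_id, at_e$player_id)
  tibble::tibble(
    player_id = keep$player_id,
    skill = at_e$mu[m],
    loyalty = keep$loyalty,
    tob = keep$tob,
    faithfulness = keep$faithfulness
  )
}

#' Fit the cross-sectional behaviour model
#'
#' Ordinary least squares of skill on loyalty, TOB and faithfulness
#' (with intercept), reporting classical standard errors, two-sided t
#' tests and per-covariate variance inflation factors.
#'
#' @param table A cross-sectional table (see [cross_section_table()]),
#'   or any data frame with columns `skill, loyalty, tob,
#'   faithfulness`.
#' @return An object of class `effect_fit`: a list with a `terms`
#'   tibble (`term, estimate, std_error, t_value, p_value`), a `vif`
#'   named vector, `n` and `sigma`.
#' @export
fit_cross_section <- function(table) {
  need <- c("skill", "loyalty", "tob", "faithfulness")
  stopifnot(all(need %in% names(table)))
  d <- table[stats::complete.cases(table[need]), need, drop = FALSE]
  if (nrow(d) <= 4) stop("need more observations than model terms")
  X <- stats::model.matrix(~ loyalty + tob + faithfulness, data = d)
  if (qr(X)$rank < ncol(X)) {
    cors <- stats::cor(X[, -1, drop = FALSE])
    diag(cors) <- 0
    bad <- which(abs(abs(cors) - 1) < 1e-12, arr.ind = TRUE)
    nm <- if (nrow(bad) > 0) {
      paste(unique(rownames(cors)[bad[, 1]]), collapse = ", ")
    } else "unknown"
    stop("rank-deficient design; collinear columns: ", nm)
  }
  fit <- stats::lm(skill ~ loyalty + tob + faithfulness, data = d)
  co <- summary(fit)$coefficients
  structure(list(
    terms = tibble::tibble(
      term = c("intercept", "loyalty", "tob", "faithfulness"),
      estimate = unname(co[, 1]),
      std_error = unname(co[, 2]),
      t_value = unname(co[, 3]),
      p_value = unname(co[, 4])
    ),
    vif = variance_inflation(d[, c("loyalty", "tob", "faithfulness")]),
    n = nrow(d),
    sigma = summary(fit)$sigma
  ), class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("Cross-sectional behaviour model (OLS, n = %d)\n", x$n))
  print(as.data.frame(x$terms), row.names = FALSE, digits = 4)
  cat("VIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing
#' covariate k on all the others (with intercept). Values near 1
#' indicate no collinearity.
#'
#' @param covariates A data frame of numeric covariate columns.
#' @return A named numeric vector of VIFs, one per column.
#' @export
variance_inflation <- function(covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(ncol(covariates) >= 2)
  vapply(names(covariates), function(k) {
    fit <- stats::lm(stats::reformulate(setdiff(names(covariates), k),
                                        response = k),
                     data = covariates)
    r2 <- summary(fit)$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Loyalty threshold where the TOB contribution reverses
#'
#' In the cross-sectional model the TOB terms contribute
#' `beta_tob * TOB + beta_faith * loyalty * TOB`; the contribution
#' changes sign at `loyalty = -beta_tob / beta_faith`. A negative TOB
#' main effect with a positive faithfulness interaction therefore turns
#' positive for loyalty above the threshold.
#'
#' @param fit Either an `effect_fit` (from [fit_cross_section()]) or
#'   the numeric `beta_tob` coefficient.
#' @param beta_faith The faithfulness coefficient (only when `fit` is
#'   numeric); must be nonzero.
#' @return The loyalty threshold. A warning is issued when it lies
#'   outside \[0, 1\] (no reversal in the admissible range).
#' @export
tob_reversal_threshold <- function(fit, beta_faith = NULL) {
  if (inherits(fit, "effect_fit")) {
    est <- fit$terms$estimate
    names(est) <- fit$terms$term
    beta_tob <- est[["tob"]]
    beta_faith <- est[["faithfulness"]]
  } else {
    beta_tob <- fit
    if (is.null(beta_faith)) stop("beta_faith is required")
  }
  if (beta_faith == 0) stop("threshold undefined: faithfulness coefficient is zero")
  thr <- -beta_tob / beta_faith
  if (thr < 0 || thr > 1) {
    warning(sprintf("no reversal in [0, 1] (threshold %.4f)", thr))
  }
  thr
}

#' Fit the overall longitudinal mixed model
#'
#' REML fit of
#' `log10(skill) ~ log10(experience) * loyalty * tob + (1 | player)`
#' on per-game rows restricted to the given experience window. The
#' fixed-effect structure contains the full three-way interaction:
#' `exp, loyal, tob, exp:loyal, exp:tob, loyal:tob, exp:loyal:tob`.
#' Wald confidence intervals are reported at `conf_level` (default 99%)
#' together with the random-intercept variance and the normalized
#' (tsp-scale) estimates.
#'
#' @param data A data frame with columns `player, experience, loyalty,
#'   tob, skill` — one row per player-game.
#' @param experience_range Window of experience kept, default
#'   `c(10, 500)`.
#' @param conf_level Confidence level for the Wald intervals.
#'   Default 0.99.
#' @return An object of class `mixed_fit`: a list with a `terms`
#'   tibble (`term, estimate, ci_low, ci_high, t_value, normalized`),
#'   `group_var`, `residual_var`, `n_groups`, `n_obs`, `conf_level`
#'   and the underlying `lmerMod` as `model`.
#' @export
fit_mixed <- function(data, experience_range = c(10, 500),
                      conf_level = 0.99) {
  need <- c("player", "experience", "loyalty", "tob", "skill")
  stopifnot(all(need %in% names(data)))
  d <- data[data$experience >= experience_range[1] &
              data$experience <= experience_range[2], , drop = FALSE]
  d <- d[stats::complete.cases(d[need]), , drop = FALSE]
  if (nrow(d) == 0) stop("no rows in the experience window")
  if (any(d$skill <= 0)) stop("skill must be positive (log10 response)")
  md <- data.frame(
    log_skill = log10(d$skill),
    exp = log10(d$experience),
    loyal = d$loyalty,
    tob = d$tob,
    player = as.factor(d$player)
  )
  for (v in c("exp", "loyal", "tob")) {
    if (stats::var(md[[v]]) == 0) {
      stop("rank-deficient design: '", v, "' is constant")
    }
  }
  fit <- lme4::lmer(log_skill ~ exp * loyal * tob + (1 | player),
                    data = md, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) {
    stop("mixed model did not converge: ",
         paste(unlist(conv$messages), collapse = "; "))
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  vc <- as.data.frame(lme4::VarCorr(fit))
  norm <- normalize_estimates(fe[1], fe[-1])
  terms <- tibble::tibble(
    term = c("intercept", names(fe)[-1]),
    estimate = unname(fe),
    ci_low = unname(fe - z * se),
    ci_high = unname(fe + z * se),
    t_value = unname(fe / se),
    normalized = unname(norm)
  )
  structure(list(
    terms = terms,
    group_var = vc$vcov[vc$grp == "player"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    n_groups = lme4::ngrps(fit)[["player"]],
    n_obs = nrow(md),
    conf_level = conf_level,
    model = fit
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Longitudinal mixed model (REML), %d obs, %d players\n",
    x$n_obs, x$n_groups))
  df <- as.data.frame(x$terms)
  df$normalized <- round(df$normalized, 2)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("Group (player) var: %.4g   Residual var: %.4g\n",
              x$group_var, x$residual_var))
  invisible(x)
}

#' Normalized (tsp-scale) estimates of the log10 mixed model
#'
#' Back-transforms log10-scale estimates to TrueSkill points: the
#' intercept becomes `10^I`, and every other term `c` becomes
#' `10^(I + c) - 10^I`, the tsp change the term induces at the
#' intercept. The inverse, `c = log10(normalized + 10^I) - I`, holds
#' exactly.
#'
#' @param intercept The log10-scale intercept I.
#' @param estimates Named numeric vector of the remaining log10-scale
#'   estimates. May be empty.
#' @return A named numeric vector: first the normalized intercept, then
#'   one entry per term. Round to 2 decimals for reporting.
#' @export
normalize_estimates <- function(intercept, estimates = numeric()) {
  base <- 10^intercept
  out <- c(intercept = unname(base), 10^(intercept + estimates) - base)
  if (length(estimates) > 0 && !is.null(names(estimates))) {
    names(out)[-1] <- names(estimates)
  }
  out
}
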