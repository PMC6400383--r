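#' End-to-end analysis pipeline
#'
#' File-based orchestration of the full analysis: simulate (or ingest)
#' a game history, rate it, compute behaviour profiles, aggregate
#' learning curves with law-of-practice fits, fit the behaviour-effect
#' models, and assemble a run report. Each stage reads and writes plain
#' files (JSONL / CSV / JSON), is idempotent given identical inputs and
#' seeds, and logs row counts at its boundaries so filters are
#' auditable. All randomness flows from the single configuration seed:
#' the population generator uses `seed` and the match simulator
#' `seed + 1`; the analysis stages are deterministic.
#'
#' @name pipeline
#' @keywords internal
NULL

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

load_sim_config <- function(config) {
  if (inherits(config, "simulation_config")) return(config)
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    vals <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config)
    }
    config <- vals
  }
  if (is.list(config)) {
    known <- names(formals(simulation_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown) > 0) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    return(do.call(simulation_config, config))
  }
  stop("config must be a simulation_config, a list, or a file path")
}

#' Pipeline stage: simulate a synthetic world
#'
#' @param config A [simulation_config()], a plain list of its
#'   arguments, or the path of a JSON/YAML file holding them.
#' @param out_dir Output directory (created if needed); writes
#'   `games.jsonl`, `truth.csv` and `config.json`.
#' @return Invisibly, the named vector of written paths.
#' @export
pipeline_simulate <- function(config, out_dir) {
  config <- load_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_games(config)
  paths <- c(games = file.path(out_dir, "games.jsonl"),
             truth = file.path(out_dir, "truth.csv"),
             config = file.path(out_dir, "config.json"))
  write_games(sim$games, paths["games"], "jsonl")
  write_truth(sim$population, config, paths["truth"])
  jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  pipeline_log("simulate", "%d games, %d players -> %s",
               nrow(sim$games), nrow(sim$population), out_dir)
  invisible(paths)
}

#' Pipeline stage: rate a game history
#'
#' @param games_path Path of a JSONL or CSV game history.
#' @param out_path Output CSV of trajectories (`player_id, seq,
#'   experience, mu, sigma`).
#' @param format Input dialect, `"jsonl"` or `"csv"`.
#' @inheritParams rate_history
#' @return Invisibly, `out_path`.
#' @export
pipeline_rate <- function(games_path, out_path, format = c("jsonl", "csv"),
                          mu0 = 25, sigma0 = 25 / 3, beta = 25 / 6,
                          tau = 0) {
  games <- read_games(games_path, match.arg(format))
  traj <- rate_history(games, mu0 = mu0, sigma0 = sigma0, beta = beta,
                       tau = tau)
  utils::write.csv(
    traj[, c("player_id", "seq", "experience", "mu", "sigma")],
    out_path, row.names = FALSE)
  pipeline_log("rate", "%d games -> %d trajectory rows (%d players) -> %s",
               nrow(games), nrow(traj), length(unique(traj$player_id)),
               out_path)
  invisible(out_path)
}

#' Pipeline stage: behaviour profiles
#'
#' @inheritParams pipeline_rate
#' @param out_path Output CSV of per-player profiles.
#' @return Invisibly, `out_path`.
#' @export
pipeline_metrics <- function(games_path, out_path,
                             format = c("jsonl", "csv")) {
  games <- read_games(games_path, match.arg(format))
  prof <- behavior_profiles(build_histories(games))
  utils::write.csv(prof, out_path, row.names = FALSE)
  pipeline_log("metrics", "%d players profiled (%d eligible) -> %s",
               nrow(prof), sum(prof$eligible), out_path)
  invisible(out_path)
}

read_trajectories <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(player_id = "character")))
}

#' Pipeline stage: learning curves and power-law fits
#'
#' Builds activity cohorts, aggregates each cohort's pseudomedian
#' learning curve over its members' first `2^n` games, and fits the law
#' of practice to every cohort curve.
#'
#' @inheritParams pipeline_rate
#' @param trajectories_path CSV written by [pipeline_rate()].
#' @param out_dir Output directory; writes `curves.csv` and
#'   `fits.json`.
#' @param min_exponent Smallest cohort exponent (see
#'   [activity_cohorts()]).
#' @param fit_min_experience Lower edge of the fitted experience window
#'   (the first games are dominated by the rating prior; see the
#'   package vignette). Default 16.
#' @return Invisibly, the named vector of written paths.
#' @export
pipeline_curves <- function(games_path, trajectories_path, out_dir,
                            format = c("jsonl", "csv"), min_exponent = 3,
                            fit_min_experience = 16) {
  games <- read_games(games_path, match.arg(format))
  traj <- read_trajectories(trajectories_path)
  histories <- build_histories(games)
  cohorts <- activity_cohorts(histories, min_exponent = min_exponent)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- list()
  fits <- list()
  for (co in unique(cohorts$cohort)) {
    members <- cohorts$player_id[cohorts$cohort == co]
    limit <- cohorts$limit[match(co, cohorts$cohort)]
    cv <- aggregate_curve(traj, players = members, max_experience = limit)
    cv$cohort <- co
    curves[[co]] <- cv
    if (limit > fit_min_experience && nrow(cv) >= 2) {
      fit <- fit_power_law(cv, c(min(fit_min_experience, limit / 2), limit))
      fits[[co]] <- list(alpha = fit$alpha, alpha_se = fit$alpha_se,
                         skill0 = fit$skill0, r2 = fit$r_squared,
                         n_players = length(members))
    }
  }
  curves <- do.call(rbind, curves)
  paths <- c(curves = file.path(out_dir, "curves.csv"),
             fits = file.path(out_dir, "fits.json"))
  utils::write.csv(
    curves[, c("cohort", "experience", "n_obs", "pseudomedian",
               "ci_low", "ci_high")], paths["curves"], row.names = FALSE)
  jsonlite::write_json(fits, paths["fits"], auto_unbox = TRUE, digits = NA)
  pipeline_log("curves", "%d cohorts, %d curve points -> %s",
               length(unique(cohorts$cohort)), nrow(curves), out_dir)
  invisible(paths)
}

#' Pipeline stage: behaviour-effect models
#'
#' Fits the cross-sectional model at each requested experience (with
#' VIF diagnostics and the TOB-reversal threshold) and the overall
#' longitudinal mixed model with its normalized estimates, writing one
#' JSON document.
#'
#' @inheritParams pipeline_curves
#' @param out_path Output JSON path.
#' @param experiences Experience values for the cross-sectional fits.
#'   Default `seq(100, 1300, by = 100)`, silently truncated to values
#'   the population reaches.
#' @param experience_range Experience window for the mixed model.
#' @param covariates Covariate convention, `"running"` or `"final"`.
#' @return Invisibly, the report list written to `out_path`.
#' @export
pipeline_effects <- function(games_path, trajectories_path, out_path,
                             format = c("jsonl", "csv"),
                             experiences = seq(100, 1300, by = 100),
                             experience_range = c(10, 500),
                             covariates = "running") {
  games <- read_games(games_path, match.arg(format))
  traj <- read_trajectories(trajectories_path)
  histories <- build_histories(games)
  max_exp <- max(traj$experience)
  experiences <- experiences[experiences <= max_exp]
  if (length(experiences) == 0) {
    stop("no requested experience level is reached by any player ",
         "(max experience ", max_exp, ")")
  }
  cross <- list()
  for (e in experiences) {
    tab <- cross_section_table(histories, traj, e, covariates = covariates)
    if (nrow(tab) <= 8) {
      pipeline_log("effects", "experience %d: only %d qualifying players, skipped",
                   e, nrow(tab))
      next
    }
    fit <- fit_cross_section(tab)
    est <- stats::setNames(fit$terms$estimate, fit$terms$term)
    thr <- withCallingHandlers(
      tob_reversal_threshold(fit),
      warning = function(w) invokeRestart("muffleWarning"))
    cross[[as.character(e)]] <- list(
      experience = e, n = fit$n,
      terms = fit$terms, vif = as.list(fit$vif),
      reversal_threshold = thr,
      reversal_in_range = thr >= 0 && thr <= 1,
      faithfulness_boost = unname(est["faithfulness"])
    )
  }
  run <- running_profiles(histories)
  prof <- behavior_profiles(histories)
  eligible <- prof$player_id[prof$eligible]
  rows <- run[run$player_id %in% eligible, , drop = FALSE]
  key_t <- paste(traj$player_id, traj$experience)
  m <- match(paste(rows$player_id, rows$experience), key_t)
  mix_tab <- data.frame(player = rows$player_id,
                        experience = rows$experience,
                        loyalty = rows$run_loyalty,
                        tob = rows$run_tob,
                        skill = traj$mu[m])
  mixed_out <- NULL
  if (sum(mix_tab$experience >= experience_range[1] &
            mix_tab$experience <= experience_range[2], na.rm = TRUE) > 50) {
    mf <- fit_mixed(mix_tab, experience_range = experience_range)
    mixed_out <- list(terms = mf$terms, group_var = mf$group_var,
                      residual_var = mf$residual_var,
                      n_groups = mf$n_groups, n_obs = mf$n_obs)
  } else {
    pipeline_log("effects", "too few rows in [%d, %d]; mixed model skipped",
                 experience_range[1], experience_range[2])
  }
  report <- list(cross_section = cross, mixed = mixed_out,
                 covariates = covariates)
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  pipeline_log("effects", "%d cross-sectional fits%s -> %s", length(cross),
               if (is.null(mixed_out)) "" else " + mixed model", out_path)
  invisible(report)
}

#' Run the full pipeline
#'
#' simulate -> rate -> metrics -> curves -> effects -> report, all under
#' one output directory. Rerunning with the same configuration (and
#' seed) reproduces every number.
#'
#' @inheritParams pipeline_simulate
#' @param out_dir Output directory for all stage files.
#' @param experiences Passed to [pipeline_effects()].
#' @return Invisibly, the run report list (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         experiences = seq(100, 1300, by = 100)) {
  config <- load_sim_config(config)
  paths <- pipeline_simulate(config, out_dir)
  traj_path <- file.path(out_dir, "trajectories.csv")
  pipeline_rate(paths["games"], traj_path, beta = config$beta)
  pipeline_metrics(paths["games"], file.path(out_dir, "profiles.csv"))
  pipeline_curves(paths["games"], traj_path, out_dir)
  pipeline_effects(paths["games"], traj_path,
                   file.path(out_dir, "effects.json"),
                   experiences = experiences)
  pipeline_report(out_dir)
}

#' Assemble the run report
#'
#' Collects the stage outputs under a run directory into one JSON
#' report: the configuration echo, per-stage row counts, the
#' law-of-practice fits, the effect fits with thresholds and normalized
#' estimates, and the seed.
#'
#' @param run_dir A directory previously populated by the pipeline
#'   stages.
#' @return Invisibly, the report list (written to `report.json`).
#' @export
pipeline_report <- function(run_dir) {
  need <- c("config.json", "games.jsonl", "trajectories.csv",
            "profiles.csv", "curves.csv", "effects.json")
  have <- file.exists(file.path(run_dir, need))
  if (!all(have)) {
    stop("run directory is missing: ",
         paste(need[!have], collapse = ", "))
  }
  config <- jsonlite::fromJSON(file.path(run_dir, "config.json"))
  profiles <- utils::read.csv(file.path(run_dir, "profiles.csv"))
  curves <- utils::read.csv(file.path(run_dir, "curves.csv"))
  effects <- jsonlite::fromJSON(file.path(run_dir, "effects.json"),
                                simplifyDataFrame = TRUE)
  report <- list(
    config = config,
    seed = config$seed,
    counts = list(
      games = length(readLines(file.path(run_dir, "games.jsonl"))),
      players_profiled = nrow(profiles),
      players_eligible = sum(profiles$eligible),
      curve_points = nrow(curves)
    ),
    power_law = jsonlite::fromJSON(file.path(run_dir, "fits.json")),
    effects = effects
  )
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log("report", "-> %s", file.path(run_dir, "report.json"))
  invisible(report)
}
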