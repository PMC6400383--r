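#' Chronological game histories
#'
#' A game history is a tibble with one row per game and columns
#' `game_id` (character), `seq` (integer chronological index, >= 0),
#' `teams` (list column; each element is a list of character vectors of
#' player ids, one vector per team) and `outcome` (list column; each
#' element is an integer permutation of the team positions, winner
#' first, 1-based). A game is a *team game* when at least one of its
#' teams has two or more members. Draws do not occur: `outcome` is
#' always a strict ranking.
#'
#' @name game-records
#' @keywords internal
NULL

# Escape a character vector for embedding in a JSON string literal.
json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

new_games <- function(game_id, seq, teams, outcome) {
  tibble::tibble(
    game_id = as.character(game_id),
    seq = as.integer(seq),
    teams = teams,
    outcome = outcome
  )
}

#' Validate a game history
#'
#' Checks the structural invariants of a game history: at least two
#' nonempty, pairwise disjoint teams per game, and an outcome that is a
#' strict ranking (a permutation of the team positions — ties are
#' rejected because the model assigns draws probability zero).
#'
#' @param games A game-history tibble (see [read_games()]).
#' @return `games`, invisibly, if valid; otherwise an error is thrown
#'   naming the offending game.
#' @export
validate_games <- function(games) {
  stopifnot(is.data.frame(games))
  need <- c("game_id", "seq", "teams", "outcome")
  missing_cols <- setdiff(need, names(games))
  if (length(missing_cols) > 0) {
    stop("game history is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(games))) {
    ts <- games$teams[[i]]
    o <- games$outcome[[i]]
    id <- games$game_id[[i]]
    if (length(ts) < 2) {
      stop("game '", id, "': needs at least two teams")
    }
    sizes <- lengths(ts)
    if (any(sizes == 0)) {
      stop("game '", id, "': every team must be nonempty")
    }
    players <- unlist(ts, use.names = FALSE)
    if (anyDuplicated(players)) {
      stop("game '", id, "': teams overlap (player '",
           players[duplicated(players)][1], "' appears in more than one team)")
    }
    if (length(o) != length(ts) || anyNA(o) ||
        !setequal(as.integer(o), seq_along(ts))) {
      stop("game '", id, "': outcome must be a permutation of the team ",
           "positions with no ties")
    }
  }
  invisible(games)
}

#' Read a chronological game history
#'
#' Reads a stream of game records from one of two supported dialects
#' and returns it sorted by the chronological index `seq` (ties in
#' `seq` keep file order). Structural invariants are checked with
#' [validate_games()].
#'
#' * `"jsonl"`: one JSON object per line, e.g.
#'   `{"game_id":"g1","seq":0,"teams":[["a","b"],["c","d"]],"outcome":[1,0]}`.
#'   `outcome` holds 0-based team indices, winner first (converted to
#'   1-based positions internally).
#' * `"csv"`: long format with columns `game_id, seq, team_index,
#'   player_id, rank` — one row per player-game, `team_index` 0-based,
#'   `rank` 1 for the winning team.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` or `"csv"`.
#' @return A validated game-history tibble (possibly empty).
#' @export
read_games <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  games <- switch(format,
    jsonl = read_games_jsonl(path),
    csv = read_games_csv(path)
  )
  if (nrow(games) > 0 && is.unsorted(games$seq)) {
    warning("games were not in chronological order; re-sorted by seq")
    games <- games[order(games$seq), , drop = FALSE]
  }
  validate_games(games)
  games
}

read_games_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(new_games(character(), integer(), list(), list()))
  }
  recs <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                       simplifyVector = FALSE),
    error = function(e) {
      # one malformed line breaks the batch parse; locate it for the report
      bad <- which(vapply(lines, function(l) {
        inherits(tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
                          error = function(e) e), "error")
      }, logical(1), USE.NAMES = FALSE))
      stop("malformed JSON on line(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  )
  n <- length(recs)
  teams <- vector("list", n)
  outcome <- vector("list", n)
  game_id <- character(n)
  seqv <- integer(n)
  for (i in seq_len(n)) {
    r <- recs[[i]]
    if (is.null(r$game_id) || is.null(r$seq) || is.null(r$teams) ||
        is.null(r$outcome)) {
      stop("line ", i, ": record must have game_id, seq, teams, outcome")
    }
    game_id[i] <- as.character(r$game_id)
    seqv[i] <- as.integer(r$seq)
    teams[[i]] <- lapply(r$teams, function(t) {
      vapply(t, as.character, character(1), USE.NAMES = FALSE)
    })
    outcome[[i]] <- vapply(r$outcome, as.integer, integer(1),
                           USE.NAMES = FALSE) + 1L
  }
  new_games(game_id, seqv, teams, outcome)
}

read_games_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(game_id = "character",
                                       player_id = "character"))
  need <- c("game_id", "seq", "team_index", "player_id", "rank")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("csv dialect requires columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(new_games(character(), integer(), list(), list()))
  }
  # preserve first-appearance order of games, then sort on seq later
  gkey <- factor(df$game_id, levels = unique(df$game_id))
  by_game <- split(df, gkey)
  n <- length(by_game)
  teams <- vector("list", n)
  outcome <- vector("list", n)
  game_id <- character(n)
  seqv <- integer(n)
  for (i in seq_len(n)) {
    g <- by_game[[i]]
    game_id[i] <- g$game_id[1]
    seqv[i] <- as.integer(g$seq[1])
    tidx <- sort(unique(as.integer(g$team_index)))
    teams[[i]] <- lapply(tidx, function(t) g$player_id[g$team_index == t])
    ranks <- vapply(tidx, function(t) {
      r <- unique(as.integer(g$rank[g$team_index == t]))
      if (length(r) != 1) {
        stop("game '", g$game_id[1], "': inconsistent rank within a team")
      }
      r
    }, integer(1))
    if (anyDuplicated(ranks)) {
      stop("game '", game_id[i], "': tied outcome (draws are not allowed)")
    }
    outcome[[i]] <- order(ranks)
  }
  new_games(game_id, seqv, teams, outcome)
}

#' Write a game history
#'
#' Inverse of [read_games()]; writing then re-reading a valid history
#' is field-identical.
#'
#' @param games A validated game-history tibble.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_games <- function(games, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_games(games)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(games)), function(i) {
      ts <- vapply(games$teams[[i]], function(t) {
        paste0('["', paste(json_escape(t), collapse = '","'), '"]')
      }, character(1))
      sprintf('{"game_id":"%s","seq":%d,"teams":[%s],"outcome":[%s]}',
              json_escape(games$game_id[i]), games$seq[i],
              paste(ts, collapse = ","),
              paste(games$outcome[[i]] - 1L, collapse = ","))
    }, character(1))
    writeLines(lines, path)
  } else {
    long <- games_participants(games)
    rank_of <- function(outcome) {
      r <- integer(length(outcome)); r[outcome] <- seq_along(outcome); r
    }
    ranks <- lapply(games$outcome, rank_of)
    offset <- cumsum(lengths(ranks)) - lengths(ranks)
    long$rank <- unlist(ranks, use.names = FALSE)[offset[long$game_row] + long$team]
    out <- data.frame(game_id = long$game_id, seq = long$seq,
                      team_index = long$team - 1L,
                      player_id = long$player_id, rank = long$rank)
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

# Long participant table: one row per player-game, in input (seq) order.
# Internal workhorse for build_histories() and the behaviour metrics.
games_participants <- function(games) {
  n_teams <- lengths(games$teams)
  sizes_by_team <- lapply(games$teams, lengths)
  team_sizes <- unlist(sizes_by_team, use.names = FALSE)
  players <- unlist(games$teams, use.names = FALSE)
  game_row <- rep(seq_len(nrow(games)), vapply(sizes_by_team, sum, numeric(1)))
  team <- rep(sequence(n_teams), team_sizes)
  tibble::tibble(
    game_row = game_row,
    game_id = games$game_id[game_row],
    seq = games$seq[game_row],
    team = team,
    team_size = rep(team_sizes, team_sizes),
    player_id = players
  )
}

#' Build per-player histories
#'
#' Expands a game history into a long table with one row per
#' player-game, in chronological order, carrying each player's running
#' experience index (1 for their first game), the team-game flag (the
#' game has at least one team of two or more members), their own team's
#' size and whether their team won.
#'
#' @param games A validated game-history tibble.
#' @return A tibble with columns `player_id, game_id, seq, experience,
#'   team, team_size, team_game, won, teammates` (a list column of the
#'   player's own-team partners in that game), sorted by `seq` and
#'   grouped implicitly by player through `experience`. Players absent
#'   from all games do not appear.
#' @export
build_histories <- function(games) {
  validate_games(games)
  long <- games_participants(games)
  if (nrow(long) == 0) {
    return(tibble::tibble(player_id = character(), game_id = character(),
                          seq = integer(), experience = integer(),
                          team = integer(), team_size = integer(),
                          team_game = logical(), won = logical(),
                          teammates = list()))
  }
  max_size <- vapply(games$teams, function(ts) max(lengths(ts)), numeric(1))
  winner_team <- vapply(games$outcome, `[`, integer(1), 1L)
  long$team_game <- max_size[long$game_row] >= 2
  long$won <- long$team == winner_team[long$game_row]
  # own-team members (excluding self), so any subset of rows still
  # carries the partner information
  n <- nrow(long)
  key <- paste(long$game_row, long$team)
  grp <- cumsum(!duplicated(key))
  sizes <- tabulate(grp)
  starts <- cumsum(sizes) - sizes + 1L
  times <- rep(sizes, sizes)
  focal <- rep(seq_len(n), times)
  combo_grp <- rep(seq_along(sizes), sizes^2)
  partner <- starts[combo_grp] - 1L + sequence(times)
  keep <- focal != partner
  long$teammates <- split(long$player_id[partner[keep]],
                          factor(focal[keep], levels = seq_len(n)))
  names(long$teammates) <- NULL
  # experience: running count of games per player, in stream order
  pid <- factor(long$player_id, levels = unique(long$player_id))
  ord <- order(pid, seq_len(nrow(long)))
  exp_sorted <- sequence(tabulate(pid))
  experience <- integer(nrow(long))
  experience[ord] <- exp_sorted
  long$experience <- experience
  long[, c("player_id", "game_id", "seq", "experience", "team",
           "team_size", "team_game", "won", "teammates")]
}
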