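#' @title Event extraction from game logs
#' @description Converts game logs into the per-trial observation/decision
#'   streams the learning model consumes. A *zap opportunity* is a
#'   (turn, target) pair where the deciding player shares a row or column with
#'   the target; an *avoidance* is a move made while able to zap and not
#'   closest to any star. Aggregate behavioural measures (zap rates, time-bin
#'   rates, cross-path rates) are computed from the same definitions.
#' @name event_extraction
NULL

#' Do two grid positions share a row or column?
#'
#' @param pos_a,pos_b Length-2 integer vectors `(row, col)`.
#' @return `TRUE` iff the positions share a row or a column.
#' @export
shared_line <- function(pos_a, pos_b) {
  pos_a[1] == pos_b[1] || pos_a[2] == pos_b[2]
}

# rebuild a stargrid_state from one log record (pre-action snapshot)
rec_state <- function(log, i) {
  grid_state(log$pos[[i]], stars = log$stars[[i]],
             timeout = log$timeout[[i]], score = log$score[[i]],
             round = log$round[i])
}

# is `actor` the unique minimum-Manhattan-distance active player to ANY star?
unique_closest_to_any_star <- function(pos, stars, actor) {
  if (nrow(stars) == 0) return(FALSE)
  act <- which(!is.na(pos[, 1]))
  others <- setdiff(act, actor)
  d_actor <- star_dists(pos[actor, ], stars)
  if (!length(others)) return(TRUE)
  op <- pos[others, , drop = FALSE]
  for (s in seq_len(nrow(stars))) {
    if (d_actor[s] < min(dist_to_cell(op, stars[s, ]))) return(TRUE)
  }
  FALSE
}

# ids of active players sharing a row/column with `actor`
line_mates <- function(pos, actor) {
  others <- setdiff(which(!is.na(pos[, 1])), actor)
  others[pos[others, 1] == pos[actor, 1] | pos[others, 2] == pos[actor, 2]]
}

# classification shared by extraction and the online model agent
classify_record <- function(pos, stars, actor, action, zapped) {
  if (action == "zap" && length(zapped) > 0) return("zap")
  if (action == "move" &&
      length(line_mates(pos, actor)) > 0 &&
      !unique_closest_to_any_star(pos, stars, actor)) {
    return("avoid")
  }
  "none"
}

#' Classify an observed action as zap, avoid, or none
#'
#' An action is a `zap` when the actor emitted a ray that hit someone; an
#' `avoid` when the actor moved while sharing a row or column with at least
#' one active player *and* was not the unique closest player to any star
#' (no learning signal arises from star-directed moves or from turns without
#' a zap opportunity).
#'
#' @param log A `stargrid_log`.
#' @param turn Round index.
#' @param actor Player id; must have acted on that round (a player in
#'   time-out yields `"none"`).
#' @return `"zap"`, `"avoid"` or `"none"`.
#' @export
classify_observed_action <- function(log, turn, actor) {
  i <- which(log$round == turn & log$actor == actor)
  if (!length(i)) return("none")
  i <- i[1]
  classify_record(log$pos[[i]], log$stars[[i]], actor, log$action[i], log$zapped[[i]])
}

participant_id <- function(log) {
  players <- attr(log, "players")
  players$player_id[players$role == "participant"][1]
}

# scaled distance to the nearest star; an empty board counts as maximally far
nearest_star_dist <- function(p, stars, grid_size) {
  d <- star_dists(p, stars)
  if (!length(d)) 2 * (grid_size - 1) else min(d)
}

#' Extract the participant's zap-opportunity decisions
#'
#' One row per (turn, candidate target) pair where the participant shared a
#' row or column with an active player, with covariates computed from the
#' pre-move state: `star_dist` (Manhattan distance to the nearest star) and
#' `target_dist` (Manhattan distance to the target), both divided by the
#' configured `distance_divisor`. `choice` is 1 when the participant's zap
#' ray actually hit that target on that turn.
#'
#' @param log A `stargrid_log`.
#' @param participant Player id of the decider; defaults to the roster's
#'   participant slot.
#' @return A tibble with columns `turn`, `observer`, `target`, `relation`,
#'   `could_zap`, `observed_action`, `choice`, `star_dist`, `target_dist`,
#'   ordered by turn then target id.
#' @export
extract_participant_decisions <- function(log, participant = NULL) {
  participant <- participant %||% participant_id(log)
  config <- attr(log, "config")
  players <- attr(log, "players")
  divisor <- config$distance_divisor
  G <- config$grid_size
  rel <- stats::setNames(players$relation, players$player_id)

  idx <- which(log$actor == participant)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    pos <- log$pos[[i]]
    cands <- sort(line_mates(pos, participant))
    if (!length(cands)) next
    me <- pos[participant, ]
    sd <- nearest_star_dist(me, log$stars[[i]], G) / divisor
    zapped <- log$zapped[[i]]
    choice <- as.integer(log$action[i] == "zap" & cands %in% zapped)
    out[[j]] <- tibble::tibble(
      turn = log$round[i], observer = participant, target = cands,
      relation = unname(rel[as.character(cands)]),
      could_zap = TRUE,
      observed_action = ifelse(choice == 1L, "zap", "none"),
      choice = choice,
      star_dist = sd,
      target_dist = dist_to_cell(pos[cands, , drop = FALSE], me) / divisor
    )
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(turn = integer(), observer = integer(), target = integer(),
                          relation = character(), could_zap = logical(),
                          observed_action = character(), choice = integer(),
                          star_dist = double(), target_dist = double())
  }
  attr(res, "divisor") <- divisor
  res
}

#' Build the chronological event stream for the learning model
#'
#' Interleaves, in game order, (a) *observations*: other players' actions
#' classified as zap or avoid (the learner watches every player, including
#' bot-versus-bot behaviour), and (b) *decisions*: the participant's own zap
#' opportunities from [extract_participant_decisions()]. Within a turn the
#' acting player's behaviour is observed (beliefs updated) before any later
#' decision is evaluated, matching the sequential structure of the game.
#'
#' @inheritParams extract_participant_decisions
#' @return A tibble of class `stargrid_events` with columns `type`
#'   (`"obs"`/`"dec"`), `turn`, `player` (actor or target), `relation`,
#'   `action` (`"zap"`/`"avoid"` for observations), `choice`, `star_dist`,
#'   `target_dist`. Attributes: `participant`, `players`, `teammates` (named
#'   list mapping each player to their same-team partners, participant
#'   excluded), `divisor`.
#' @export
build_event_stream <- function(log, participant = NULL) {
  participant <- participant %||% participant_id(log)
  players <- attr(log, "players")
  rel <- stats::setNames(players$relation, players$player_id)
  rows <- vector("list", nrow(log))
  for (i in seq_len(nrow(log))) {
    actor <- log$actor[i]
    if (actor == participant) {
      next  # decisions added below, keyed by record index
    }
    cls <- classify_record(log$pos[[i]], log$stars[[i]], actor,
                           log$action[i], log$zapped[[i]])
    if (cls == "none") next
    rows[[i]] <- tibble::tibble(
      .rec = i, type = "obs", turn = log$round[i], player = actor,
      relation = unname(rel[as.character(actor)]), action = cls,
      choice = NA_integer_, star_dist = NA_real_, target_dist = NA_real_
    )
  }
  obs <- dplyr::bind_rows(rows)
  dec <- extract_participant_decisions(log, participant)
  if (nrow(dec)) {
    rec_of_turn <- stats::setNames(
      which(log$actor == participant),
      log$round[log$actor == participant]
    )
    dec <- tibble::tibble(
      .rec = unname(rec_of_turn[as.character(dec$turn)]),
      type = "dec", turn = dec$turn, player = dec$target,
      relation = dec$relation, action = dec$observed_action,
      choice = dec$choice, star_dist = dec$star_dist,
      target_dist = dec$target_dist
    )
  }
  ev <- dplyr::bind_rows(obs, dec)
  if (nrow(ev)) {
    ev <- dplyr::arrange(ev, .data$.rec, .data$player)
    ev$.rec <- NULL
  } else {
    ev <- tibble::tibble(type = character(), turn = integer(), player = integer(),
                         relation = character(), action = character(),
                         choice = integer(), star_dist = double(),
                         target_dist = double())
  }
  mates <- team_mates(players, participant)
  structure(ev, participant = participant, players = players,
            teammates = mates, divisor = attr(dec, "divisor") %||%
              attr(log, "config")$distance_divisor,
            class = c("stargrid_events", class(ev)))
}

# named list: player id -> same-team partners (participant excluded)
team_mates <- function(players, participant) {
  ids <- players$player_id[players$player_id != participant]
  mates <- lapply(ids, function(p) {
    same <- players$player_id[players$team == players$team[players$player_id == p]]
    setdiff(same, c(p, participant))
  })
  stats::setNames(mates, ids)
}

join_target_info <- function(dec, players) {
  info <- dplyr::select(players, target = "player_id", behavior = "policy")
  dplyr::left_join(dec, info, by = "target")
}

#' Zap rates by group identity and bot behaviour
#'
#' The zapping rate is the proportion of zap opportunities on which the
#' participant zapped. The default denominator counts (turn, target)
#' opportunity pairs, matching the unit of the model likelihood;
#' `denominator = "turns"` counts distinct turns per target instead.
#'
#' @inheritParams extract_participant_decisions
#' @param denominator `"pairs"` (default) or `"turns"`.
#' @return A tibble with one row per relation-by-behaviour cell: `n_zaps`,
#'   `n_opportunities`, `rate` (`NA` when a cell has no opportunities).
#' @export
zap_rate <- function(log, participant = NULL, denominator = c("pairs", "turns")) {
  denominator <- match.arg(denominator)
  dec <- extract_participant_decisions(log, participant)
  players <- attr(log, "players")
  dec <- join_target_info(dec, players)
  cells <- dplyr::distinct(
    dplyr::select(
      join_target_info(tibble::tibble(target = players$player_id[players$role == "bot"]),
                       players),
      "target", "behavior"
    )
  )
  cells$relation <- players$relation[match(cells$target, players$player_id)]
  if (denominator == "pairs") {
    per_target <- dplyr::summarise(
      dplyr::group_by(dec, .data$target),
      n_zaps = sum(.data$choice), n_opportunities = dplyr::n(), .groups = "drop"
    )
  } else {
    per_target <- dplyr::summarise(
      dplyr::group_by(dec, .data$target),
      n_zaps = dplyr::n_distinct(.data$turn[.data$choice == 1L]),
      n_opportunities = dplyr::n_distinct(.data$turn), .groups = "drop"
    )
  }
  out <- dplyr::left_join(cells, per_target, by = "target")
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$relation, .data$behavior),
    n_zaps = sum(.data$n_zaps, na.rm = TRUE),
    n_opportunities = sum(.data$n_opportunities, na.rm = TRUE),
    .groups = "drop"
  )
  out$rate <- ifelse(out$n_opportunities > 0, out$n_zaps / out$n_opportunities, NA_real_)
  out
}

#' Zap rates in consecutive time bins
#'
#' @inheritParams zap_rate
#' @param bin_size Turns per bin (default 25, giving four bins over a
#'   100-turn game). A trailing partial bin is kept and flagged via the
#'   `truncated_last_bin` attribute.
#' @return A tibble of per-bin relation-by-behaviour rates.
#' @export
time_binned_rates <- function(log, participant = NULL, bin_size = 25) {
  dec <- extract_participant_decisions(log, participant)
  players <- attr(log, "players")
  config <- attr(log, "config")
  dec <- join_target_info(dec, players)
  dec$bin <- (dec$turn - 1L) %/% bin_size + 1L
  out <- dplyr::summarise(
    dplyr::group_by(dec, .data$bin, .data$relation, .data$behavior),
    n_zaps = sum(.data$choice), n_opportunities = dplyr::n(), .groups = "drop"
  )
  out$rate <- ifelse(out$n_opportunities > 0, out$n_zaps / out$n_opportunities, NA_real_)
  attr(out, "truncated_last_bin") <- config$n_turns %% bin_size != 0
  out
}

#' Cross-path rates by group identity and bot behaviour
#'
#' A participant move *crosses the path* of another player when it ends on a
#' cell sharing a row or column with that player (making the participant
#' zappable on the next turn). For each target the rate is normalised by the
#' number of participant moves on which crossing that target was possible,
#' i.e. some available move (including a blocked no-op) would have ended on a
#' shared line.
#'
#' @inheritParams zap_rate
#' @return A tibble of per-cell rates (`NA` when crossing was never possible).
#' @export
cross_path_rate <- function(log, participant = NULL) {
  participant <- participant %||% participant_id(log)
  config <- attr(log, "config")
  players <- attr(log, "players")
  idx <- which(log$actor == participant & log$action == "move")
  counts <- list()
  for (i in idx) {
    st <- rec_state(log, i)
    me <- st$pos[participant, ]
    landings <- lapply(DIRECTIONS, function(d) {
      if (move_blocked(st, participant, d, config$grid_size)) me
      else me + .dir_delta[d, ]
    })
    actual <- if (move_blocked(st, participant, log$dir[i], config$grid_size)) {
      me
    } else {
      me + .dir_delta[log$dir[i], ]
    }
    others <- setdiff(active_players(st), participant)
    for (o in others) {
      op <- st$pos[o, ]
      possible <- any(vapply(landings, function(l) shared_line(l, op), logical(1)))
      if (!possible) next
      key <- as.character(o)
      prev <- counts[[key]] %||% c(crossed = 0L, possible = 0L)
      prev["possible"] <- prev["possible"] + 1L
      if (shared_line(actual, op)) prev["crossed"] <- prev["crossed"] + 1L
      counts[[key]] <- prev
    }
  }
  ids <- as.integer(names(counts))
  out <- tibble::tibble(
    target = ids,
    relation = players$relation[match(ids, players$player_id)],
    behavior = players$policy[match(ids, players$player_id)],
    n_crossed = vapply(counts, `[[`, integer(1), "crossed"),
    n_possible = vapply(counts, `[[`, integer(1), "possible")
  )
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$relation, .data$behavior),
    n_crossed = sum(.data$n_crossed), n_possible = sum(.data$n_possible),
    .groups = "drop"
  )
  out$rate <- ifelse(out$n_possible > 0, out$n_crossed / out$n_possible, NA_real_)
  out
}
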