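#' @title Star-harvest game engine
#' @description Deterministic-given-seed implementation of the star-harvest
#'   grid game: five players move around a square grid collecting stars, and
#'   may sacrifice a move to "zap" other players, sending everyone caught in
#'   the ray to a time-out zone for a fixed number of turns. Two scripted bot
#'   policies (zappers and avoiders) seek stars and differ only in how they
#'   resolve competition over a star.
#' @name game_engine
NULL

DIRECTIONS <- c("up", "down", "left", "right")

.dir_delta <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(DIRECTIONS, c("row", "col")))

#' Construct a game action
#'
#' @param kind `"move"` or `"zap"`.
#' @param dir One of `"up"`, `"down"`, `"left"`, `"right"`.
#' @return A `stargrid_action`.
#' @export
game_action <- function(kind = c("move", "zap"), dir) {
  kind <- match.arg(kind)
  if (length(dir) != 1 || !dir %in% DIRECTIONS) {
    stop("dir must be one of ", paste(DIRECTIONS, collapse = ", "))
  }
  structure(list(kind = kind, dir = dir), class = "stargrid_action")
}

#' Default five-player roster
#'
#' Player 1 is the participant slot. In the `groups` condition players 2-3
#' share the participant's team colour (ingroup) and players 4-5 belong to the
#' other team (outgroup); in the `neutral` condition every player has a
#' distinct colour. The behaviour mix assigns bot policies: `mixed` makes one
#' zapper and one avoider per team (players 2 and 4 zap).
#'
#' @param group_type `"groups"` or `"neutral"`.
#' @param behavior_mix `"mixed"`, `"all_zappers"` or `"all_avoiders"`.
#' @param participant_policy Policy label recorded for the participant slot;
#'   `"avoider"` is a star-seeking placeholder used for bot-only logs, and
#'   `"model_agent"` marks a slot to be driven by [make_model_agent()].
#' @return A tibble with columns `player_id`, `role`, `policy`, `team`,
#'   `relation`.
#' @export
default_players <- function(group_type = c("groups", "neutral"),
                            behavior_mix = c("mixed", "all_zappers", "all_avoiders"),
                            participant_policy = "avoider") {
  group_type <- match.arg(group_type)
  behavior_mix <- match.arg(behavior_mix)
  bot_policy <- switch(behavior_mix,
    mixed = c("zapper", "avoider", "zapper", "avoider"),
    all_zappers = rep("zapper", 4),
    all_avoiders = rep("avoider", 4)
  )
  if (group_type == "groups") {
    team <- c("blue", "blue", "blue", "orange", "orange")
    relation <- c("self", "ingroup", "ingroup", "outgroup", "outgroup")
  } else {
    team <- c("c1", "c2", "c3", "c4", "c5")
    relation <- c("self", rep("neutral", 4))
  }
  tibble::tibble(
    player_id = 1:5,
    role = c("participant", rep("bot", 4)),
    policy = c(participant_policy, bot_policy),
    team = team,
    relation = relation
  )
}

#' Game configuration
#'
#' @param grid_size Cells per side of the square grid.
#' @param n_players Number of players.
#' @param n_turns Number of rounds in a game.
#' @param star_spawn_prob Probability that one new star appears after each
#'   round.
#' @param star_expire_prob Per-star, per-round probability that an uncollected
#'   star disappears.
#' @param timeout_turns Rounds a zapped player spends in the time-out zone.
#' @param group_type,behavior_mix Condition labels, see [default_players()].
#' @param turn_order Permutation of player ids giving the fixed within-round
#'   acting order.
#' @param seed Integer seed driving every random draw of the game.
#' @param zap_ray `"through"` (the ray hits every active player on the line,
#'   the default) or `"first"` (only the nearest player is hit).
#' @param distance_divisor Divisor applied to raw Manhattan distances before
#'   they enter the decision rule (default 10, the grid side).
#' @param n_stars_init Stars placed on the board before the first round.
#' @param players Roster tibble; defaults to
#'   `default_players(group_type, behavior_mix)`.
#' @return A `stargrid_config` list.
#' @export
game_config <- function(grid_size = 10, n_players = 5, n_turns = 100,
                        star_spawn_prob = 0.75, star_expire_prob = 0.05,
                        timeout_turns = 3,
                        group_type = c("groups", "neutral"),
                        behavior_mix = c("mixed", "all_zappers", "all_avoiders"),
                        turn_order = seq_len(n_players), seed = 1L,
                        zap_ray = c("through", "first"),
                        distance_divisor = 10, n_stars_init = 1,
                        players = NULL) {
  group_type <- match.arg(group_type)
  behavior_mix <- match.arg(behavior_mix)
  zap_ray <- match.arg(zap_ray)
  stopifnot(
    grid_size >= 4, n_players >= 2, n_turns >= 1,
    star_spawn_prob >= 0, star_spawn_prob <= 1,
    star_expire_prob >= 0, star_expire_prob <= 1,
    timeout_turns >= 1
  )
  if (!setequal(turn_order, seq_len(n_players)) || length(turn_order) != n_players) {
    stop("turn_order must be a permutation of 1..n_players")
  }
  players <- players %||% default_players(group_type, behavior_mix)
  stopifnot(nrow(players) == n_players)
  structure(list(
    grid_size = as.integer(grid_size), n_players = as.integer(n_players),
    n_turns = as.integer(n_turns),
    star_spawn_prob = star_spawn_prob, star_expire_prob = star_expire_prob,
    timeout_turns = as.integer(timeout_turns),
    group_type = group_type, behavior_mix = behavior_mix,
    turn_order = as.integer(turn_order), seed = as.integer(seed),
    zap_ray = zap_ray, distance_divisor = distance_divisor,
    n_stars_init = as.integer(n_stars_init),
    players = players
  ), class = "stargrid_config")
}

# empty star matrix helper
no_stars <- function() matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))

#' Create a grid state
#'
#' Positions use 0-based coordinates, `(row, col)` with the origin at the top
#' left; a player in the time-out zone has an `NA` position and a positive
#' `timeout` counter.
#'
#' @param pos Integer matrix `n_players x 2` of positions (NA rows allowed).
#' @param stars Integer matrix `m x 2` of star cells.
#' @param timeout Integer vector of remaining time-out rounds.
#' @param score Integer vector of collected stars.
#' @param round Current round index (1-based).
#' @param fresh Logical vector marking players zapped during the current round
#'   (their counter is not decremented until the following round ends).
#' @return A `stargrid_state`.
#' @export
grid_state <- function(pos, stars = no_stars(),
                       timeout = integer(nrow(pos)),
                       score = integer(nrow(pos)),
                       round = 1L, fresh = logical(nrow(pos))) {
  pos <- matrix(as.integer(pos), ncol = 2, dimnames = list(NULL, c("row", "col")))
  stars <- matrix(as.integer(stars), ncol = 2, dimnames = list(NULL, c("row", "col")))
  st <- structure(list(pos = pos, stars = stars,
                       timeout = as.integer(timeout), score = as.integer(score),
                       round = as.integer(round), fresh = fresh),
                  class = "stargrid_state")
  validate_state(st)
  st
}

validate_state <- function(state, grid_size = NULL) {
  act <- active_players(state)
  if (length(act) > 1) {
    cells <- state$pos[act, 1] * 1e6 + state$pos[act, 2]
    if (anyDuplicated(cells)) stop("active players must occupy distinct cells")
  }
  if (any(state$timeout < 0)) stop("timeout counters must be non-negative")
  if (!is.null(grid_size) &&
      any(stats::na.omit(c(state$pos)) < 0 | stats::na.omit(c(state$pos)) >= grid_size)) {
    stop("positions must lie within the grid")
  }
  invisible(state)
}

#' Active (on-grid) players of a state
#' @param state A `stargrid_state`.
#' @return Integer vector of player ids currently on the grid.
#' @export
active_players <- function(state) which(!is.na(state$pos[, 1]))

manhattan <- function(a, b) abs(a[1] - b[1]) + abs(a[2] - b[2])

# Manhattan distance from each row of `pos` to `cell`
dist_to_cell <- function(pos, cell) abs(pos[, 1] - cell[1]) + abs(pos[, 2] - cell[2])

# distance from point `p` to every star; numeric(0) when the board is empty
star_dists <- function(p, stars) {
  if (nrow(stars) == 0) return(numeric(0))
  abs(stars[, 1] - p[1]) + abs(stars[, 2] - p[2])
}

cell_free <- function(state, cell) {
  act <- active_players(state)
  if (length(act) &&
      any(state$pos[act, 1] == cell[1] & state$pos[act, 2] == cell[2])) return(FALSE)
  if (nrow(state$stars) &&
      any(state$stars[, 1] == cell[1] & state$stars[, 2] == cell[2])) return(FALSE)
  TRUE
}

free_cells <- function(state, grid_size) {
  occ <- rbind(state$pos[active_players(state), , drop = FALSE], state$stars)
  all_ids <- seq_len(grid_size^2) - 1L
  occ_ids <- if (nrow(occ)) occ[, 1] * grid_size + occ[, 2] else integer(0)
  setdiff(all_ids, occ_ids)
}

move_blocked <- function(state, self_id, dir, grid_size) {
  target <- state$pos[self_id, ] + .dir_delta[dir, ]
  if (any(target < 0) || any(target >= grid_size)) return(TRUE)
  others <- setdiff(active_players(state), self_id)
  if (length(others) &&
      any(state$pos[others, 1] == target[1] & state$pos[others, 2] == target[2])) {
    return(TRUE)
  }
  FALSE
}

#' Apply one player action to a grid state
#'
#' A move shifts the actor one cell unless blocked by the grid edge or an
#' occupied cell (blocked moves leave the position unchanged); landing on a
#' star collects it. A zap leaves the actor in place and sends every active
#' player on the straight line in the zap direction to the time-out zone
#' (`timeout_turns` rounds, position removed from the grid); with
#' `config$zap_ray = "first"` only the nearest player on the line is hit.
#' The input state is not modified.
#'
#' @param state A `stargrid_state`.
#' @param actor Id of the acting player (must be active).
#' @param act A [game_action()].
#' @param config A [game_config()].
#' @return A new `stargrid_state`, with attributes `zapped` (integer ids hit)
#'   and `star_collected` (logical).
#' @export
apply_action <- function(state, actor, act, config) {
  if (is.na(state$pos[actor, 1])) stop("actor ", actor, " is in the time-out zone")
  if (!inherits(act, "stargrid_action")) stop("act must be a stargrid_action")
  G <- config$grid_size
  zapped <- integer(0)
  star_collected <- FALSE

  if (act$kind == "move") {
    if (!move_blocked(state, actor, act$dir, G)) {
      state$pos[actor, ] <- state$pos[actor, ] + .dir_delta[act$dir, ]
      if (nrow(state$stars)) {
        hit <- state$stars[, 1] == state$pos[actor, 1] &
          state$stars[, 2] == state$pos[actor, 2]
        if (any(hit)) {
          state$stars <- state$stars[!hit, , drop = FALSE]
          state$score[actor] <- state$score[actor] + 1L
          star_collected <- TRUE
        }
      }
    }
  } else {
    me <- state$pos[actor, ]
    others <- setdiff(active_players(state), actor)
    if (length(others)) {
      op <- state$pos[others, , drop = FALSE]
      in_ray <- switch(act$dir,
        up    = op[, 2] == me[2] & op[, 1] < me[1],
        down  = op[, 2] == me[2] & op[, 1] > me[1],
        left  = op[, 1] == me[1] & op[, 2] < me[2],
        right = op[, 1] == me[1] & op[, 2] > me[2]
      )
      zapped <- others[in_ray]
      if (config$zap_ray == "first" && length(zapped) > 1) {
        d <- dist_to_cell(state$pos[zapped, , drop = FALSE], me)
        zapped <- zapped[which.min(d)]
      }
      if (length(zapped)) {
        state$timeout[zapped] <- config$timeout_turns
        state$fresh[zapped] <- TRUE
        state$pos[zapped, ] <- NA_integer_
      }
    }
  }
  attr(state, "zapped") <- zapped
  attr(state, "star_collected") <- star_collected
  state
}

#' Advance the board between rounds
#'
#' Called once after all active players have acted. Random draws happen in a
#' fixed order: (1) with probability `star_spawn_prob` one star is added at a
#' uniformly random cell free of players and stars; (2) each star that was
#' already on the board before the spawn disappears independently with
#' probability `star_expire_prob`; (3) time-out counters of players zapped in
#' earlier rounds are decremented, and players reaching 0 re-enter at a
#' uniformly random free cell (players zapped during the round just played
#' keep their full counter). If no free cell exists a spawn is skipped and a
#' re-entry is retried next round.
#'
#' @inheritParams apply_action
#' @return A new `stargrid_state` with `round` incremented.
#' @export
advance_round <- function(state, config) {
  G <- config$grid_size
  n_pre <- nrow(state$stars)

  if (config$star_spawn_prob > 0 && stats::runif(1) < config$star_spawn_prob) {
    free <- free_cells(state, G)
    if (length(free)) {
      cell_id <- free[sample.int(length(free), 1)]
      state$stars <- rbind(state$stars,
                           c(cell_id %/% G, cell_id %% G))
    }
  }

  if (n_pre > 0 && config$star_expire_prob > 0) {
    gone <- stats::runif(n_pre) < config$star_expire_prob
    keep <- c(!gone, rep(TRUE, nrow(state$stars) - n_pre))
    state$stars <- state$stars[keep, , drop = FALSE]
  }

  for (pid in seq_along(state$timeout)) {
    if (state$timeout[pid] > 0 && !state$fresh[pid]) {
      state$timeout[pid] <- state$timeout[pid] - 1L
      if (state$timeout[pid] == 0L) {
        free <- free_cells(state, G)
        if (length(free)) {
          cell_id <- free[sample.int(length(free), 1)]
          state$pos[pid, ] <- c(cell_id %/% G, cell_id %% G)
        } else {
          state$timeout[pid] <- 1L  # retry next round
        }
      }
    }
  }
  state$fresh[] <- FALSE
  state$round <- state$round + 1L
  state
}

# first direction of a distance-reducing step toward `cell`, trying the row
# axis before the column axis and falling back to a blocked (no-op) move
move_toward <- function(state, self_id, cell, config) {
  me <- state$pos[self_id, ]
  cands <- character(0)
  if (cell[1] < me[1]) cands <- c(cands, "up")
  if (cell[1] > me[1]) cands <- c(cands, "down")
  if (cell[2] < me[2]) cands <- c(cands, "left")
  if (cell[2] > me[2]) cands <- c(cands, "right")
  if (!length(cands)) return(random_legal_move(state, self_id, config))
  for (d in cands) {
    if (!move_blocked(state, self_id, d, config$grid_size)) return(game_action("move", d))
  }
  game_action("move", cands[1])
}

# move maximizing Manhattan distance from `other_id`; ties resolved in the
# fixed direction order (row axis before column axis)
move_away <- function(state, self_id, other_id, config) {
  me <- state$pos[self_id, ]
  other <- state$pos[other_id, ]
  best_dir <- DIRECTIONS[1]
  best_d <- -1
  for (d in DIRECTIONS) {
    land <- if (move_blocked(state, self_id, d, config$grid_size)) me else me + .dir_delta[d, ]
    dd <- manhattan(land, other)
    if (dd > best_d) {
      best_d <- dd
      best_dir <- d
    }
  }
  game_action("move", best_dir)
}

random_legal_move <- function(state, self_id, config) {
  legal <- DIRECTIONS[!vapply(DIRECTIONS, move_blocked,
                              logical(1), state = state,
                              self_id = self_id, grid_size = config$grid_size)]
  if (!length(legal)) return(game_action("move", "up"))
  game_action("move", legal[sample.int(length(legal), 1)])
}

# shared star-seeking cascade of the two bot policies; returns either an
# action (steps i, iii, iv) or the context of a competition (step ii)
bot_cascade <- function(state, self_id, config) {
  me <- state$pos[self_id, ]
  stars <- state$stars
  if (nrow(stars) == 0) {
    return(list(action = random_legal_move(state, self_id, config)))
  }
  others <- setdiff(active_players(state), self_id)
  d_self <- star_dists(me, stars)
  d_other_min <- rep(Inf, nrow(stars))
  if (length(others)) {
    op <- state$pos[others, , drop = FALSE]
    for (s in seq_len(nrow(stars))) {
      d_other_min[s] <- min(dist_to_cell(op, stars[s, ]))
    }
  }
  mine <- which(d_self < d_other_min)
  if (length(mine)) {
    target <- mine[which.min(d_self[mine])]
    return(list(action = move_toward(state, self_id, stars[target, ], config)))
  }
  ns <- which.min(d_self)  # nearest star, lowest index on ties
  competitors <- integer(0)
  if (length(others)) {
    d_comp <- dist_to_cell(state$pos[others, , drop = FALSE], stars[ns, ])
    competitors <- others[d_comp < d_self[ns]]
  }
  shared <- competitors[state$pos[competitors, 1] == me[1] |
                          state$pos[competitors, 2] == me[2]]
  if (length(shared)) {
    return(list(competition = TRUE, rival = min(shared), nearest_star = ns,
                d_self = d_self, d_other_min = d_other_min))
  }
  list(action = move_toward(state, self_id, stars[ns, ], config))
}

zap_direction <- function(me, other) {
  if (me[1] == other[1]) {
    if (other[2] > me[2]) "right" else "left"
  } else {
    if (other[1] > me[1]) "down" else "up"
  }
}

#' Zapper bot policy
#'
#' Star-seeking bot that zaps under competition. In order: (i) if the bot is
#' strictly the closest active player to some star, move one step toward the
#' nearest such star; (ii) otherwise, if a player strictly closer than the bot
#' to the bot's nearest star shares its row or column, zap toward that player
#' (lowest id on ties); (iii) otherwise move toward the nearest star; (iv)
#' with no stars on the board, move in a uniformly random legal direction.
#' All distances are Manhattan; movement prefers the row axis.
#'
#' @inheritParams apply_action
#' @param self_id Id of the deciding bot (must be active).
#' @return A [game_action()].
#' @export
zapper_policy <- function(state, self_id, config) {
  res <- bot_cascade(state, self_id, config)
  if (!is.null(res$action)) return(res$action)
  game_action("zap", zap_direction(state$pos[self_id, ], state$pos[res$rival, ]))
}

#' Avoider bot policy
#'
#' Identical cascade to [zapper_policy()] except under competition (step ii):
#' instead of zapping, the bot moves toward the nearest star for which it is
#' itself the closest player; if no such star exists it moves to maximise the
#' Manhattan distance from the competing player. Never zaps.
#'
#' @inheritParams zapper_policy
#' @return A [game_action()] of kind `"move"`.
#' @export
avoider_policy <- function(state, self_id, config) {
  res <- bot_cascade(state, self_id, config)
  if (!is.null(res$action)) return(res$action)
  alt <- which(res$d_self <= res$d_other_min)
  if (length(alt)) {
    target <- alt[which.min(res$d_self[alt])]
    return(move_toward(state, self_id, state$stars[target, ], config))
  }
  move_away(state, self_id, res$rival, config)
}

resolve_policy <- function(p, config) {
  if (is.character(p)) {
    switch(p,
      zapper = list(act = function(state, self_id) zapper_policy(state, self_id, config)),
      avoider = list(act = function(state, self_id) avoider_policy(state, self_id, config)),
      stop("policy '", p, "' needs an explicit function or agent")
    )
  } else if (is.function(p)) {
    list(act = p)
  } else if (is.list(p) && is.function(p$act)) {
    p
  } else {
    stop("invalid policy specification")
  }
}

init_state <- function(config) {
  G <- config$grid_size
  cells <- sample.int(G^2, config$n_players) - 1L
  pos <- cbind(cells %/% G, cells %% G)
  state <- grid_state(pos)
  if (config$n_stars_init > 0) {
    free <- free_cells(state, G)
    star_cells <- free[sample.int(length(free), min(config$n_stars_init, length(free)))]
    state$stars <- cbind(row = star_cells %/% G, col = star_cells %% G)
  }
  state
}

#' Play a full game and return its log
#'
#' Plays `config$n_turns` rounds in the fixed turn order, recording one row
#' per player action; players in the time-out zone emit no record. The single
#' seeded generator makes identical `(config, policies, seed)` produce
#' byte-identical logs.
#'
#' @param config A [game_config()].
#' @param policies Optional named-by-position list overriding the roster's
#'   policies: `"zapper"`, `"avoider"`, a `function(state, self_id)` returning
#'   a [game_action()], or an agent list with fields `act` and (optionally)
#'   `observe` as produced by [make_model_agent()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble of class `stargrid_log` with columns `round`, `actor`,
#'   `action`, `dir`, `zapped` (list), `star_collected`, and list columns
#'   `pos`, `timeout`, `score`, `stars` holding the pre-action state.
#'   The configuration and roster are attached as attributes.
#' @export
run_game <- function(config, policies = NULL, seed = config$seed) {
  set.seed(seed)
  pol <- vector("list", config$n_players)
  for (i in seq_len(config$n_players)) {
    spec <- if (!is.null(policies) && !is.null(policies[[i]])) policies[[i]] else config$players$policy[i]
    pol[[i]] <- resolve_policy(spec, config)
  }
  observers <- which(vapply(pol, function(p) is.function(p$observe), logical(1)))

  state <- init_state(config)
  recs <- vector("list", config$n_turns * config$n_players)
  k <- 0L
  for (round in seq_len(config$n_turns)) {
    for (pid in config$turn_order) {
      if (state$timeout[pid] > 0) next
      act <- pol[[pid]]$act(state, pid)
      if (!inherits(act, "stargrid_action")) {
        stop("policy for player ", pid, " returned an invalid action")
      }
      pre <- state
      state <- apply_action(state, pid, act, config)
      k <- k + 1L
      rec <- list(round = round, actor = pid,
                  action = act$kind, dir = act$dir,
                  zapped = attr(state, "zapped"),
                  star_collected = attr(state, "star_collected"),
                  pos = pre$pos, timeout = pre$timeout,
                  score = pre$score, stars = pre$stars)
      recs[[k]] <- rec
      for (ob in observers) pol[[ob]]$observe(rec)
    }
    state <- advance_round(state, config)
  }
  recs <- recs[seq_len(k)]
  log <- tibble::tibble(
    round = vapply(recs, `[[`, integer(1), "round"),
    actor = vapply(recs, `[[`, integer(1), "actor"),
    action = vapply(recs, `[[`, character(1), "action"),
    dir = vapply(recs, `[[`, character(1), "dir"),
    zapped = lapply(recs, `[[`, "zapped"),
    star_collected = vapply(recs, `[[`, logical(1), "star_collected"),
    pos = lapply(recs, `[[`, "pos"),
    timeout = lapply(recs, `[[`, "timeout"),
    score = lapply(recs, `[[`, "score"),
    stars = lapply(recs, `[[`, "stars")
  )
  attr(log, "config") <- config
  attr(log, "players") <- config$players
  attr(log, "final_state") <- state
  class(log) <- c("stargrid_log", class(log))
  log
}

#' @export
print.stargrid_log <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<stargrid_log> %d records, %d rounds, %s/%s condition\n",
              nrow(x), cfg$n_turns, cfg$group_type, cfg$behavior_mix))
  NextMethod()
}
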