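#' @title Synthetic participants and studies
#' @description Generates complete synthetic datasets: bot-only game logs,
#'   replay-based model predictions (running the learning model against
#'   recorded bot behaviour while ignoring the logged participant's choices),
#'   and closed-loop games in which the participant slot is driven by the
#'   decision model itself with known parameters — the ground truth for
#'   parameter- and model-recovery experiments.
#' @name synthetic_data
NULL

#' Default group-level generating parameters
#'
#' A plausible population for synthetic studies: an overall reluctance to zap
#' (negative bias), an outgroup prior exceeding the ingroup prior, much
#' faster learning from zaps than from avoidances, a strong positive weight
#' on the learned zap belief, distance weights making zaps more likely when
#' stars are far and targets close, and modest attribution rates with
#' near-zero attribution of outgroup avoidances.
#'
#' @return Named numeric vector of the 14 model parameters on the natural
#'   scale (rates on the probability scale).
#' @export
default_group_params <- function() {
  c(bias = -1.01, prior_in = -0.87, prior_out = -0.12,
    w_star = 0.26, w_target = -1.84, w_zap = 0.89,
    lr_zap_in = 0.71, lr_zap_out = 0.84,
    lr_avoid_in = 0.08, lr_avoid_out = 0.13,
    at_zap_in = 0.19, at_zap_out = 0.22,
    at_avoid_in = 0.14, at_avoid_out = 0.02)
}

#' Default group-level standard deviations
#'
#' Between-participant heterogeneity on the sampling scale (rates on the
#' logit scale): 0.5 for every parameter, a moderate spread typical of
#' individual differences in trial-by-trial learning models.
#'
#' @return Named numeric vector of 14 sampling-scale standard deviations.
#' @export
default_group_sd <- function() {
  stats::setNames(rep(0.5, 14), param_names())
}

#' Create a model-driven participant agent
#'
#' A closed-loop analogue of a human participant: the agent watches every
#' other player's action, classifies it as zap/avoid with the same rule used
#' by event extraction, and updates its beliefs online (per the chosen
#' variant). On its own turn it evaluates each candidate target it shares a
#' row or column with, in random order, drawing a Bernoulli zap decision at
#' the model's probability; the first success emits a zap in that target's
#' direction, otherwise the agent moves by the avoider policy.
#'
#' @param params A [model_params()] object.
#' @param variant `"P"`, `"PL"` or `"PLA"`.
#' @param config The [game_config()] the agent will play in.
#' @param self_id Player id of the agent slot.
#' @return An agent list with `act` and `observe` functions, usable as a
#'   policy in [run_game()].
#' @export
make_model_agent <- function(params, variant = "PLA", config, self_id = 1L) {
  params <- variant_params(params, variant)
  players <- config$players
  rel <- stats::setNames(players$relation, players$player_id)
  mates <- team_mates(players, self_id)
  beliefs <- stats::setNames(numeric(nrow(players)), players$player_id)
  env <- environment()

  observe <- function(rec) {
    if (rec$actor == self_id) return(invisible(NULL))
    cls <- classify_record(rec$pos, rec$stars, rec$actor, rec$action, rec$zapped)
    if (cls == "none") return(invisible(NULL))
    key <- as.character(rec$actor)
    r <- rel[key]
    env$beliefs[key] <- update_actor_belief(env$beliefs[key], cls, r, params)
    for (m in mates[[key]]) {
      mk <- as.character(m)
      env$beliefs[mk] <- update_teammate_belief(env$beliefs[mk], cls, r, params)
    }
    invisible(NULL)
  }

  trace <- list()
  act <- function(state, id) {
    cands <- sort(line_mates(state$pos, id))
    if (length(cands)) {
      me <- state$pos[id, ]
      sd <- nearest_star_dist(me, state$stars, config$grid_size) /
        config$distance_divisor
      ord <- if (length(cands) > 1) cands[sample.int(length(cands))] else cands
      chosen <- NULL
      for (tg in ord) {
        td <- manhattan(state$pos[tg, ], me) / config$distance_divisor
        pz <- zap_probability(params, rel[as.character(tg)], sd, td,
                              env$beliefs[as.character(tg)])
        env$trace[[length(env$trace) + 1L]] <-
          list(turn = state$round, target = tg, p_zap = unname(pz))
        if (is.null(chosen) && stats::runif(1) < pz) chosen <- tg
      }
      if (!is.null(chosen)) {
        return(game_action("zap", zap_direction(me, state$pos[chosen, ])))
      }
    }
    avoider_policy(state, id, config)
  }

  structure(list(act = act, observe = observe,
                 beliefs = function() env$beliefs,
                 trace = function() dplyr::bind_rows(env$trace)),
            class = "stargrid_agent")
}

#' Simulate one model-driven participant
#'
#' Plays a full game in which the participant slot is driven by
#' [make_model_agent()] and the bots by their scripted policies.
#'
#' @param config A [game_config()].
#' @param params A [model_params()] object for the participant.
#' @param variant Model variant driving the participant.
#' @param seed Integer seed.
#' @return A `stargrid_log`.
#' @export
simulate_participant <- function(config, params, variant = "PLA",
                                 seed = config$seed) {
  pid <- config$players$player_id[config$players$role == "participant"][1]
  agent <- make_model_agent(params, variant, config, self_id = pid)
  policies <- vector("list", config$n_players)
  policies[[pid]] <- agent
  run_game(config, policies = policies, seed = seed)
}

#' Simulate a full synthetic study
#'
#' Samples per-participant parameters from independent normal group
#' distributions on the sampling scale (rates on the logit scale, then
#' transformed), plays one model-driven game per participant, and extracts
#' the event streams. The generating truth is stored alongside the data for
#' recovery scoring.
#'
#' @param n_participants Number of simulated participants.
#' @param group_mean Named natural-scale group means (see
#'   [default_group_params()]).
#' @param group_sd Named sampling-scale group sds.
#' @param variant Variant driving the simulated participants.
#' @param group_type,behavior_mix Condition of every game (default the
#'   mixed-behaviour groups condition, the one the model is fitted to).
#' @param n_turns Rounds per game.
#' @param seed Integer seed; the manifest stored in the result makes the
#'   dataset bit-reproducible.
#' @return A list of class `stargrid_study`: `logs`, `events` (per-participant
#'   streams), `participants` (tibble with the sampled parameters),
#'   `truth` (list with `group_mean_natural`, `group_mean_sampling`,
#'   `group_sd`), and `manifest`.
#' @export
simulate_study <- function(n_participants, group_mean = default_group_params(),
                           group_sd = default_group_sd(), variant = "PLA",
                           group_type = "groups", behavior_mix = "mixed",
                           n_turns = 100, seed = 1) {
  stopifnot(n_participants >= 1)
  group_mean <- group_mean[param_names()]
  group_sd <- group_sd[param_names()]
  mu_sampling <- to_sampling(group_mean)
  set.seed(seed)
  theta <- matrix(stats::rnorm(n_participants * 14), n_participants, 14)
  theta <- sweep(sweep(theta, 2, group_sd, "*"), 2, mu_sampling, "+")
  game_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)

  logs <- vector("list", n_participants)
  events <- vector("list", n_participants)
  for (j in seq_len(n_participants)) {
    pars <- params_from_vector(to_natural(theta[j, ]))
    cfg <- game_config(group_type = group_type, behavior_mix = behavior_mix,
                       n_turns = n_turns, seed = game_seeds[j])
    logs[[j]] <- simulate_participant(cfg, pars, variant, seed = game_seeds[j])
    events[[j]] <- build_event_stream(logs[[j]])
  }
  nm <- sprintf("p%03d", seq_len(n_participants))
  names(logs) <- names(events) <- nm
  participants <- tibble::tibble(
    participant = nm,
    game_seed = game_seeds,
    theta = lapply(seq_len(n_participants), function(j) theta[j, ])
  )
  structure(list(
    logs = logs, events = events, participants = participants,
    truth = list(group_mean_natural = group_mean,
                 group_mean_sampling = mu_sampling,
                 group_sd = group_sd,
                 theta_sampling = theta,
                 variant = variant),
    manifest = list(n_participants = n_participants, variant = variant,
                    group_type = group_type, behavior_mix = behavior_mix,
                    n_turns = n_turns, seed = seed)
  ), class = "stargrid_study")
}

#' @export
print.stargrid_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<stargrid_study> %d participants, %s/%s, %d turns, variant %s, seed %d\n",
              m$n_participants, m$group_type, m$behavior_mix, m$n_turns,
              m$variant, m$seed))
  invisible(x)
}

#' Replay a recorded game through the learning model
#'
#' Discards the logged participant's decisions and uses only the recorded
#' behaviour (positions, zaps, avoidances, star locations) to generate the
#' model's expected zapping behaviour: per-opportunity zap probabilities,
#' sampled zap decisions, and the underlying belief trajectories. The
#' recorded bot actions are never altered. Covariates at the participant's
#' decision points use the participant slot's recorded positions (a
#' star-seeking placeholder in bot-only logs).
#'
#' @param log A `stargrid_log`.
#' @param params A [model_params()] object.
#' @param variant Model variant.
#' @param seed Optional seed for the sampled zap decisions; `NULL` returns
#'   probabilities only.
#' @return A list of class `stargrid_replay`: `decisions` (one row per zap
#'   opportunity with `p_zap`, sampled `sim_zap`, target `relation` and
#'   `behavior`) and `trajectories` (post-event beliefs per tracked player,
#'   with the player's scripted behaviour attached).
#' @export
replay_predict <- function(log, params, variant = "PLA", seed = NULL) {
  events <- build_event_stream(log)
  fw <- forward_pass(events, params, variant)
  players <- attr(log, "players")
  dec <- fw$events[fw$events$type == "dec", ]
  dec <- dplyr::select(dec, "turn", target = "player", "relation",
                       "star_dist", "target_dist", "belief", "p_zap")
  dec$behavior <- players$policy[match(dec$target, players$player_id)]
  if (!is.null(seed)) {
    set.seed(seed)
    dec$sim_zap <- as.integer(stats::runif(nrow(dec)) < dec$p_zap)
  }
  traj <- fw$trajectories
  traj$behavior <- players$policy[match(traj$player, players$player_id)]
  traj$relation <- players$relation[match(traj$player, players$player_id)]
  structure(list(decisions = dec, trajectories = traj,
                 variant = variant),
            class = "stargrid_replay")
}

#' Parameter sets for the three simulation regimes
#'
#' Simulation regimes used to demonstrate that the model separates the three
#' learning mechanisms in the mixed-behaviour condition. `prior`: learning
#' and attribution disabled, group-identity priors low (-0.9) or high
#' (-0.1). `learning`: attribution disabled, priors 0, avoidance learning
#' rate 0.25, zap learning rate low (0.2) or high (0.9). `attribution`:
#' priors 0, zap learning rate 0.8, avoidance learning rate 0.25, avoidance
#' attribution 0, zap attribution low (0.2) or high (0.5). All regimes share
#' the situational weights (`w_star` 0.26, `w_target` -1.84, `w_zap` 0.89)
#' and a zero bias.
#'
#' @param mechanism `"prior"`, `"learning"` or `"attribution"`.
#' @param level `"low"` or `"high"`.
#' @return A [model_params()] object and its matching variant as the
#'   `"variant"` attribute.
#' @export
regime_params <- function(mechanism = c("prior", "learning", "attribution"),
                          level = c("low", "high")) {
  mechanism <- match.arg(mechanism)
  level <- match.arg(level)
  base <- list(bias = 0, w_star = 0.26, w_target = -1.84, w_zap = 0.89)
  p <- switch(mechanism,
    prior = {
      pr <- if (level == "low") -0.9 else -0.1
      c(base, list(prior_in = pr, prior_out = pr))
    },
    learning = {
      lz <- if (level == "low") 0.2 else 0.9
      c(base, list(lr_zap_in = lz, lr_zap_out = lz,
                   lr_avoid_in = 0.25, lr_avoid_out = 0.25))
    },
    attribution = {
      az <- if (level == "low") 0.2 else 0.5
      c(base, list(lr_zap_in = 0.8, lr_zap_out = 0.8,
                   lr_avoid_in = 0.25, lr_avoid_out = 0.25,
                   at_zap_in = az, at_zap_out = az))
    }
  )
  out <- do.call(model_params, p)
  attr(out, "variant") <- switch(mechanism, prior = "P", learning = "PL",
                                 attribution = "PLA")
  out
}
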