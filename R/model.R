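#' @title Trial-by-trial social-learning model
#' @description The P/PL/PLA model family. A logistic decision rule maps a
#'   zapping bias, a group-identity prior, situational distances and the
#'   learned belief that the target zaps onto the probability of zapping a
#'   candidate target. Beliefs about each player's likelihood to zap start at
#'   0 and are updated by a prediction-error rule after every observed zap
#'   (outcome 1) or avoidance (outcome 0); under the PLA variant the update
#'   also propagates, at the attribution rate, to the actor's teammates.
#' @name learning_model
NULL

#' Probability of zapping a candidate target
#'
#' The linear predictor is
#' `bias + prior(relation) + w_star * star_dist + w_target * target_dist +
#' w_zap * belief`, passed through the inverse logit. The prior term is
#' `prior_in` for ingroup targets, `prior_out` for outgroup targets, and 0
#' for neutral targets.
#'
#' @param params A [model_params()] object.
#' @param relation `"ingroup"`, `"outgroup"` or `"neutral"` (vectorised).
#' @param star_dist,target_dist Scaled Manhattan distances (non-negative).
#' @param belief Current belief in `[0, 1]` that the target zaps.
#' @return Zap probability in `(0, 1)`.
#' @export
#' @examples
#' zap_probability(model_params(), "neutral", 0, 0, 0)  # 0.5
zap_probability <- function(params, relation, star_dist, target_dist, belief) {
  if (any(!is.finite(star_dist)) || any(!is.finite(target_dist))) {
    stop("covariates must be finite")
  }
  prior <- ifelse(relation == "ingroup", params$prior_in,
                  ifelse(relation == "outgroup", params$prior_out, 0))
  eta <- params$bias + prior + params$w_star * star_dist +
    params$w_target * target_dist + params$w_zap * belief
  stats::plogis(eta)
}

#' Update the belief about the acting player
#'
#' Prediction-error update: an observed zap moves the belief toward 1 at the
#' relation-specific zap learning rate; an observed avoidance moves it toward
#' 0 at the avoidance learning rate.
#'
#' @param belief Current belief in `[0, 1]`.
#' @param observed `"zap"` or `"avoid"`.
#' @param relation Relation of the acting player to the learner.
#' @param params A [model_params()] object.
#' @return Updated belief.
#' @export
update_actor_belief <- function(belief, observed, relation, params) {
  target <- if (observed == "zap") 1 else 0
  lr <- lookup_rate(params, "lr", observed, relation)
  belief + lr * (target - belief)
}

#' Update the belief about the acting player's teammate
#'
#' Group-level attribution: the same functional form as
#' [update_actor_belief()], with the attribution rates in place of the
#' learning rates. Applies only to same-team players of the actor.
#'
#' @param belief_other Current belief about the teammate.
#' @inheritParams update_actor_belief
#' @return Updated teammate belief.
#' @export
update_teammate_belief <- function(belief_other, observed, relation, params) {
  target <- if (observed == "zap") 1 else 0
  at <- lookup_rate(params, "at", observed, relation)
  belief_other + at * (target - belief_other)
}

events_teammates <- function(events, teammates) {
  mates <- teammates %||% attr(events, "teammates")
  if (is.null(mates)) {
    ids <- sort(unique(events$player))
    mates <- stats::setNames(rep(list(integer(0)), length(ids)), ids)
  }
  mates
}

check_event_order <- function(events) {
  if (nrow(events) && is.unsorted(events$turn)) {
    stop("events must be ordered in time (non-decreasing turn)")
  }
}

#' Run the model forward over an event stream
#'
#' Processes events chronologically: each observation updates the acting
#' player's belief (and, under PLA, their teammates' beliefs); each decision
#' row is assigned the zap probability implied by the beliefs current at that
#' moment. Deterministic given its inputs.
#'
#' @param events A `stargrid_events` tibble (see [build_event_stream()]), or
#'   any tibble with the same columns.
#' @param params A [model_params()] object.
#' @param variant `"P"`, `"PL"` or `"PLA"`.
#' @param teammates Named list mapping player ids to their same-team
#'   partners; defaults to the attribute attached by [build_event_stream()].
#' @return A list of class `stargrid_forward`: `events`, the input augmented
#'   with `belief` (belief about the row's player *before* the event) and
#'   `p_zap` (decision rows); and `trajectories`, a long tibble of
#'   post-event beliefs for every tracked player.
#' @export
forward_pass <- function(events, params, variant = c("PLA", "PL", "P"),
                         teammates = NULL) {
  variant <- match.arg(variant)
  check_event_order(events)
  params <- variant_params(params, variant)
  mates <- events_teammates(events, teammates)
  ids <- sort(unique(c(events$player, as.integer(names(mates)))))
  beliefs <- stats::setNames(numeric(length(ids)), ids)

  n <- nrow(events)
  belief_col <- numeric(n)
  p_col <- rep(NA_real_, n)
  traj <- matrix(0, nrow = n, ncol = length(ids), dimnames = list(NULL, names(beliefs)))
  for (i in seq_len(n)) {
    key <- as.character(events$player[i])
    belief_col[i] <- beliefs[key]
    if (events$type[i] == "obs") {
      obs <- events$action[i]
      rel <- events$relation[i]
      beliefs[key] <- update_actor_belief(beliefs[key], obs, rel, params)
      for (m in mates[[key]]) {
        mk <- as.character(m)
        beliefs[mk] <- update_teammate_belief(beliefs[mk], obs, rel, params)
      }
    } else {
      p_col[i] <- zap_probability(params, events$relation[i],
                                  events$star_dist[i], events$target_dist[i],
                                  beliefs[key])
    }
    traj[i, ] <- beliefs
  }
  ev <- tibble::as_tibble(events)
  ev$belief <- belief_col
  ev$p_zap <- p_col
  trajectories <- tibble::tibble(
    event = rep(seq_len(n), each = length(ids)),
    turn = rep(ev$turn, each = length(ids)),
    player = rep(ids, times = n),
    belief = as.vector(t(traj))
  )
  structure(list(events = ev, trajectories = trajectories,
                 variant = variant, params = params),
            class = "stargrid_forward")
}

#' Pointwise Bernoulli log-likelihood of the participant's decisions
#'
#' One log-likelihood term per (decision, target) zap opportunity; turns on
#' which the participant could not zap contribute nothing. Probabilities are
#' clamped away from 0/1 at `1e-12`.
#'
#' @inheritParams forward_pass
#' @return Numeric vector, one element per decision row of `events`.
#' @export
pointwise_loglik <- function(events, params, variant = c("PLA", "PL", "P"),
                             teammates = NULL) {
  variant <- match.arg(variant)
  fw <- forward_pass(events, params, variant, teammates)
  dec <- fw$events[fw$events$type == "dec", ]
  if (!nrow(dec)) return(numeric(0))
  p <- pmin(pmax(dec$p_zap, 1e-12), 1 - 1e-12)
  dec$choice * log(p) + (1 - dec$choice) * log(1 - p)
}

#' @export
print.stargrid_forward <- function(x, ...) {
  nd <- sum(x$events$type == "dec")
  cat(sprintf("<stargrid_forward> variant %s: %d events (%d decisions)\n",
              x$variant, nrow(x$events), nd))
  invisible(x)
}
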