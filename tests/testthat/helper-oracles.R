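# Independent oracles and generators used across the suite.
#
# The forward-pass oracle below deliberately re-implements the belief
# recursion in a different style (an environment of per-player beliefs and
# explicit branching) so that it shares no code with the package
# implementation it checks.

oracle_rate <- function(params, kind, action, relation) {
  if (relation == "ingroup") {
    params[[paste0(kind, "_", action, "_in")]]
  } else if (relation == "outgroup") {
    params[[paste0(kind, "_", action, "_out")]]
  } else {
    (params[[paste0(kind, "_", action, "_in")]] +
       params[[paste0(kind, "_", action, "_out")]]) / 2
  }
}

# sequential re-derivation of beliefs, decision probabilities, and the
# pointwise Bernoulli log-likelihood
oracle_forward <- function(events, params, variant, teammates) {
  if (variant == "P") {
    for (nm in names(params)) if (grepl("^(lr|at)_", nm)) params[[nm]] <- 0
  }
  if (variant == "PL") {
    for (nm in names(params)) if (grepl("^at_", nm)) params[[nm]] <- 0
  }
  ids <- sort(unique(c(events$player, as.integer(names(teammates)))))
  b <- new.env()
  for (id in ids) assign(as.character(id), 0, envir = b)

  n <- nrow(events)
  belief_before <- numeric(n)
  p_zap <- rep(NA_real_, n)
  ll <- c()
  for (i in seq_len(n)) {
    id <- as.character(events$player[i])
    cur <- get(id, envir = b)
    belief_before[i] <- cur
    if (events$type[i] == "obs") {
      outcome <- if (events$action[i] == "zap") 1 else 0
      lr <- oracle_rate(params, "lr", events$action[i], events$relation[i])
      assign(id, cur + lr * (outcome - cur), envir = b)
      for (tm in teammates[[id]]) {
        tmb <- get(as.character(tm), envir = b)
        at <- oracle_rate(params, "at", events$action[i], events$relation[i])
        assign(as.character(tm), tmb + at * (outcome - tmb), envir = b)
      }
    } else {
      prior <- if (events$relation[i] == "ingroup") {
        params$prior_in
      } else if (events$relation[i] == "outgroup") {
        params$prior_out
      } else 0
      eta <- params$bias + prior +
        params$w_star * events$star_dist[i] +
        params$w_target * events$target_dist[i] +
        params$w_zap * cur
      p <- 1 / (1 + exp(-eta))
      p_zap[i] <- p
      pc <- min(max(p, 1e-12), 1 - 1e-12)
      ll <- c(ll, events$choice[i] * log(pc) + (1 - events$choice[i]) * log(1 - pc))
    }
  }
  list(belief_before = belief_before, p_zap = p_zap, loglik = ll)
}

# brute-force WAIC: explicit double loop over observations and draws
oracle_waic <- function(ll) {
  n <- ncol(ll)
  S <- nrow(ll)
  lppd_i <- numeric(n)
  p_i <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (s in seq_len(S)) tot <- tot + exp(ll[s, i])
    lppd_i[i] <- log(tot / S)
    m <- mean(ll[, i])
    acc <- 0
    for (s in seq_len(S)) acc <- acc + (ll[s, i] - m)^2
    p_i[i] <- acc / (S - 1)
  }
  waic_i <- -2 * (lppd_i - p_i)
  list(waic = sum(waic_i), p_waic = sum(p_i), lppd = sum(lppd_i),
       se = sqrt(n * stats::var(waic_i)))
}

# random event stream over four bots (two teams of two) plus teammate map
random_stream <- function(n_events = 60, p_dec = 0.4, neutral = FALSE) {
  ids <- 2:5
  relation_of <- if (neutral) {
    stats::setNames(rep("neutral", 4), ids)
  } else {
    stats::setNames(c("ingroup", "ingroup", "outgroup", "outgroup"), ids)
  }
  teammates <- if (neutral) {
    stats::setNames(rep(list(integer(0)), 4), ids)
  } else {
    list(`2` = 3L, `3` = 2L, `4` = 5L, `5` = 4L)
  }
  type <- ifelse(stats::runif(n_events) < p_dec, "dec", "obs")
  player <- sample(ids, n_events, replace = TRUE)
  ev <- tibble::tibble(
    type = type,
    turn = sort(sample.int(100, n_events, replace = TRUE)),
    player = player,
    relation = unname(relation_of[as.character(player)]),
    action = ifelse(type == "obs",
                    sample(c("zap", "avoid"), n_events, replace = TRUE),
                    NA_character_),
    choice = ifelse(type == "dec", stats::rbinom(n_events, 1, 0.3), NA_integer_),
    star_dist = ifelse(type == "dec", stats::runif(n_events, 0, 1.8), NA_real_),
    target_dist = ifelse(type == "dec", stats::runif(n_events, 0.1, 1.8), NA_real_)
  )
  structure(ev, teammates = teammates, participant = 1L,
            class = c("stargrid_events", class(ev)))
}

random_params <- function() {
  model_params(
    bias = stats::rnorm(1, 0, 1),
    prior_in = stats::rnorm(1, 0, 1), prior_out = stats::rnorm(1, 0, 1),
    w_star = stats::rnorm(1, 0, 0.5), w_target = stats::rnorm(1, 0, 0.5),
    w_zap = stats::rnorm(1, 0, 0.5),
    lr_zap_in = stats::runif(1), lr_zap_out = stats::runif(1),
    lr_avoid_in = stats::runif(1), lr_avoid_out = stats::runif(1),
    at_zap_in = stats::runif(1), at_zap_out = stats::runif(1),
    at_avoid_in = stats::runif(1), at_avoid_out = stats::runif(1)
  )
}
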