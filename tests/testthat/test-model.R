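test_that("zap probability is the inverse logit of the linear predictor", {
  expect_equal(zap_probability(model_params(), "neutral", 0, 0, 0), 0.5)
  # group-level point estimates of the decision rule, hand-evaluated
  p <- model_params(bias = -1.01, prior_out = -0.12, w_star = 0.03,
                    w_target = -0.18, w_zap = 0.89)
  expect_equal(zap_probability(p, "outgroup", 0, 0, 0), plogis(-1.13))
  # prior term: in/out/neutral
  p2 <- model_params(prior_in = -2, prior_out = 1)
  expect_equal(zap_probability(p2, "ingroup", 0, 0, 0), plogis(-2))
  expect_equal(zap_probability(p2, "neutral", 0, 0, 0), 0.5)
  # strictly increasing in the target belief when w_zap > 0
  p3 <- model_params(w_zap = 0.89)
  probs <- zap_probability(p3, "neutral", 0.3, 0.5, c(0, 0.4, 0.8, 1))
  expect_true(all(diff(probs) > 0))
  expect_error(zap_probability(p3, "neutral", Inf, 0, 0), "finite")
})

test_that("belief updates follow the prediction-error rule", {
  p <- model_params(lr_zap_in = 0.9, lr_avoid_in = 0.25)
  expect_equal(update_actor_belief(0, "zap", "ingroup", p), 0.9)
  expect_equal(update_actor_belief(0.5, "avoid", "ingroup", p), 0.375)
  # closed form: n zaps from 0 give 1 - (1 - lr)^n
  p2 <- model_params(lr_zap_out = 0.2)
  b <- 0
  path <- numeric(50)
  for (i in 1:50) {
    b <- update_actor_belief(b, "zap", "outgroup", p2)
    path[i] <- b
  }
  expect_equal(b, 1 - 0.8^50)
  expect_true(all(diff(path) > 0))
})

test_that("teammate updates use the attribution rates", {
  p0 <- model_params(lr_zap_in = 0.9)  # all attribution rates 0
  expect_equal(update_teammate_belief(0.37, "zap", "ingroup", p0), 0.37)
  # attribution equal to the learning rate: complete attribution
  p1 <- model_params(lr_zap_out = 0.6, at_zap_out = 0.6)
  b <- 0.25
  expect_equal(update_actor_belief(b, "zap", "outgroup", p1),
               update_teammate_belief(b, "zap", "outgroup", p1))
  # hand-computed single step at a fitted-scale rate
  p2 <- model_params(at_zap_out = 0.22)
  expect_equal(update_teammate_belief(0.4, "zap", "outgroup", p2), 0.532)
})

test_that("a three-observation stream matches step-by-step hand computation", {
  p <- model_params(bias = -0.5, prior_in = 0.3, prior_out = -0.2,
                    w_star = 0.4, w_target = -1.2, w_zap = 0.9,
                    lr_zap_in = 0.6, lr_zap_out = 0.8,
                    lr_avoid_in = 0.1, lr_avoid_out = 0.2,
                    at_zap_in = 0.3, at_zap_out = 0.25,
                    at_avoid_in = 0.15, at_avoid_out = 0.05)
  ev <- tibble::tibble(
    type = c("obs", "obs", "obs", "dec", "dec"),
    turn = c(1L, 2L, 3L, 4L, 4L),
    player = c(4L, 4L, 2L, 4L, 5L),
    relation = c("outgroup", "outgroup", "ingroup", "outgroup", "outgroup"),
    action = c("zap", "avoid", "zap", NA, NA),
    choice = c(NA, NA, NA, 1L, 0L),
    star_dist = c(NA, NA, NA, 0.4, 0.4),
    target_dist = c(NA, NA, NA, 0.2, 0.6)
  )
  mates <- list(`2` = 3L, `3` = 2L, `4` = 5L, `5` = 4L)
  fw <- forward_pass(ev, p, "PLA", teammates = mates)
  # beliefs: player 4: 0 -> 0.8 (zap) -> 0.8 + 0.2*(0-0.8) = 0.64
  # player 5 (teammate of 4): 0 -> 0.25 (at zap) -> 0.25 + 0.05*(0-0.25) = 0.2375
  # player 2: 0 -> 0.6; player 3 (teammate): 0 -> 0.3
  expect_equal(fw$events$belief[4], 0.64, tolerance = 1e-12)
  expect_equal(fw$events$belief[5], 0.2375, tolerance = 1e-12)
  eta4 <- -0.5 - 0.2 + 0.4 * 0.4 - 1.2 * 0.2 + 0.9 * 0.64
  eta5 <- -0.5 - 0.2 + 0.4 * 0.4 - 1.2 * 0.6 + 0.9 * 0.2375
  expect_equal(fw$events$p_zap[4], plogis(eta4), tolerance = 1e-12)
  expect_equal(fw$events$p_zap[5], plogis(eta5), tolerance = 1e-12)
  ll <- pointwise_loglik(ev, p, "PLA", teammates = mates)
  expect_equal(ll, c(log(plogis(eta4)), log(1 - plogis(eta5))), tolerance = 1e-12)
})

test_that("variant P freezes beliefs at zero", {
  set.seed(1)
  ev <- random_stream(80)
  p <- random_params()
  fw <- forward_pass(ev, p, "P")
  expect_true(all(fw$trajectories$belief == 0))
  expect_true(all(fw$events$belief == 0))
  # probabilities then depend only on priors and covariates
  dec <- fw$events[fw$events$type == "dec", ]
  pr <- ifelse(dec$relation == "ingroup", p$prior_in,
               ifelse(dec$relation == "outgroup", p$prior_out, 0))
  expect_equal(dec$p_zap,
               plogis(p$bias + pr + p$w_star * dec$star_dist +
                        p$w_target * dec$target_dist))
})

test_that("variant nesting is exact: PLA(At=0) = PL and PL(LR=0) = P", {
  set.seed(2)
  for (i in 1:20) {
    ev <- random_stream(60)
    p <- random_params()
    p_no_at <- p
    for (nm in grep("^at_", names(p), value = TRUE)) p_no_at[[nm]] <- 0
    expect_identical(forward_pass(ev, p_no_at, "PLA")$events,
                     forward_pass(ev, p_no_at, "PL")$events)
    p_no_lr <- p_no_at
    for (nm in grep("^lr_", names(p), value = TRUE)) p_no_lr[[nm]] <- 0
    expect_identical(forward_pass(ev, p_no_lr, "PL")$events,
                     forward_pass(ev, p_no_lr, "P")$events)
  }
})

test_that("beliefs stay within [0, 1] and respect monotone limits", {
  set.seed(3)
  for (i in 1:25) {
    ev <- random_stream(120, neutral = i %% 2 == 0)
    p <- random_params()
    fw <- forward_pass(ev, p, sample(c("PL", "PLA"), 1))
    expect_true(all(fw$trajectories$belief >= 0 & fw$trajectories$belief <= 1))
  }
  # only-zap observations: belief converges monotonically toward 1
  p <- model_params(lr_zap_in = 0.3)
  ev <- tibble::tibble(type = "obs", turn = 1:30, player = 2L,
                       relation = "ingroup", action = "zap",
                       choice = NA_integer_, star_dist = NA_real_,
                       target_dist = NA_real_)
  tr <- forward_pass(ev, p, "PL", teammates = list(`2` = integer(0)))$trajectories
  b2 <- tr$belief[tr$player == 2]
  expect_true(all(diff(b2) > 0))
  expect_equal(b2[30], 1 - 0.7^30)
  # only-avoid observations from initialization 0: belief stays 0
  ev$action <- "avoid"
  tr0 <- forward_pass(ev, random_params(), "PL",
                      teammates = list(`2` = integer(0)))$trajectories
  expect_true(all(tr0$belief == 0))
})

test_that("swapping group labels and parameter pairs leaves the likelihood invariant", {
  set.seed(4)
  for (i in 1:10) {
    ev <- random_stream(80)
    p <- random_params()
    swap <- function(p) {
      q <- p
      q$prior_in <- p$prior_out; q$prior_out <- p$prior_in
      for (stem in c("lr_zap", "lr_avoid", "at_zap", "at_avoid")) {
        q[[paste0(stem, "_in")]] <- p[[paste0(stem, "_out")]]
        q[[paste0(stem, "_out")]] <- p[[paste0(stem, "_in")]]
      }
      q
    }
    ev_sw <- ev
    ev_sw$relation <- ifelse(ev$relation == "ingroup", "outgroup", "ingroup")
    expect_equal(sum(pointwise_loglik(ev, p, "PLA")),
                 sum(pointwise_loglik(ev_sw, swap(p), "PLA")),
                 tolerance = 1e-12)
  }
})

test_that("the forward pass is pure and rejects out-of-order events", {
  set.seed(5)
  ev <- random_stream(50)
  p <- random_params()
  expect_identical(forward_pass(ev, p, "PLA"), forward_pass(ev, p, "PLA"))
  bad <- ev[order(ev$player), ]
  if (is.unsorted(bad$turn)) {
    expect_error(forward_pass(bad, p, "PLA"), "ordered")
  }
})

test_that("pointwise log-likelihood handles flat and empty streams", {
  # all-zero parameters and covariates: every decision has p = 0.5
  ev <- tibble::tibble(type = "dec", turn = 1:7, player = 2L,
                       relation = "neutral", action = NA_character_,
                       choice = rbinom(7, 1, 0.5), star_dist = 0, target_dist = 0)
  ll <- pointwise_loglik(ev, model_params(), "P",
                         teammates = list(`2` = integer(0)))
  expect_equal(sum(ll), -7 * log(2))
  empty <- ev[0, ]
  expect_equal(length(pointwise_loglik(empty, model_params(), "P",
                                       teammates = list(`2` = integer(0)))), 0)
})
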