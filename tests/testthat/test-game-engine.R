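cfg <- game_config(seed = 1)

test_that("zap sends every player on the ray to time-out for the full duration", {
  st <- grid_state(pos5(c(4, 4), c(4, 9), c(0, 0), c(9, 9), c(9, 0)))
  out <- apply_action(st, 1, game_action("zap", "right"), cfg)
  expect_equal(attr(out, "zapped"), 2L)
  expect_equal(out$timeout[2], 3L)
  expect_true(is.na(out$pos[2, 1]))
  expect_equal(out$pos[1, ], st$pos[1, ])  # zapper stays put

  # two players on the same line: a through ray hits both
  st2 <- grid_state(pos5(c(4, 2), c(4, 5), c(4, 8), c(0, 0), c(9, 9)))
  out2 <- apply_action(st2, 1, game_action("zap", "right"), cfg)
  expect_setequal(attr(out2, "zapped"), c(2L, 3L))
  cfg_first <- game_config(zap_ray = "first", seed = 1)
  out3 <- apply_action(st2, 1, game_action("zap", "right"), cfg_first)
  expect_equal(attr(out3, "zapped"), 2L)
})

test_that("moves are blocked at edges and occupied cells, and collect stars", {
  st <- grid_state(pos5(c(0, 0), c(0, 1), c(5, 5), c(9, 9), c(9, 0)),
                   stars = stars_at(c(2, 4)))
  # off-grid: no-op
  out <- apply_action(st, 1, game_action("move", "up"), cfg)
  expect_equal(out$pos[1, ], st$pos[1, ])
  expect_equal(nrow(out$stars), 1)
  # occupied: no-op
  out <- apply_action(st, 1, game_action("move", "right"), cfg)
  expect_equal(out$pos[1, ], st$pos[1, ])
  # star collection
  st2 <- grid_state(pos5(c(2, 3), c(0, 1), c(5, 5), c(9, 9), c(9, 0)),
                    stars = stars_at(c(2, 4)))
  out2 <- apply_action(st2, 1, game_action("move", "right"), cfg)
  expect_equal(out2$pos[1, ], c(row = 2L, col = 4L))
  expect_equal(out2$score[1], 1L)
  expect_equal(nrow(out2$stars), 0)
  expect_true(attr(out2, "star_collected"))
  # input state untouched
  expect_equal(st2$score[1], 0L)
  expect_equal(nrow(st2$stars), 1)
})

test_that("acting from time-out is a contract violation", {
  st <- grid_state(pos5(c(4, 4), c(4, 9), c(0, 0), c(9, 9), c(9, 0)))
  st$timeout[2] <- 2L
  st$pos[2, ] <- NA_integer_
  expect_error(apply_action(st, 2, game_action("move", "up"), cfg), "time-out")
  expect_error(game_action("move", "diagonal"), "dir")
})

test_that("advance_round with degenerate probabilities leaves stars unchanged", {
  cfg0 <- game_config(star_spawn_prob = 0, star_expire_prob = 0, seed = 1)
  st <- grid_state(pos5(c(4, 4), c(4, 9), c(0, 0), c(9, 9), c(9, 0)),
                   stars = stars_at(c(2, 2), c(7, 7)))
  out <- advance_round(st, cfg0)
  expect_equal(out$stars, st$stars)
  expect_equal(out$round, st$round + 1L)
})

test_that("timed-out players re-enter at a free cell when their counter expires", {
  cfg0 <- game_config(star_spawn_prob = 0, star_expire_prob = 0, seed = 1)
  st <- grid_state(pos5(c(4, 4), c(4, 9), c(0, 0), c(9, 9), c(9, 0)))
  st$timeout[2] <- 1L
  st$pos[2, ] <- NA_integer_
  set.seed(5)
  out <- advance_round(st, cfg0)
  expect_equal(out$timeout[2], 0L)
  expect_false(is.na(out$pos[2, 1]))
  # freshly zapped players keep their full counter through the round end
  st$fresh[2] <- TRUE
  st$timeout[2] <- 3L
  out2 <- advance_round(st, cfg0)
  expect_equal(out2$timeout[2], 3L)
  expect_false(out2$fresh[2])
})

test_that("long-run star spawn fraction matches the configured probability", {
  cfg0 <- game_config(star_spawn_prob = 0.75, star_expire_prob = 0, seed = 1)
  empty <- grid_state(pos5(c(0, 0), c(0, 9), c(9, 0), c(9, 9), c(5, 5)))
  set.seed(42)
  n_spawn <- 0L
  for (i in 1:10000) {
    out <- advance_round(empty, cfg0)
    n_spawn <- n_spawn + nrow(out$stars)
  }
  expect_gt(n_spawn / 10000, 0.73)
  expect_lt(n_spawn / 10000, 0.77)
})

test_that("zapper policy follows the star-seeking cascade", {
  # (i) strictly closest to a star: move toward it (same row -> step right)
  st <- grid_state(pos5(c(3, 3), c(9, 9), c(0, 0), c(9, 0), c(0, 9)),
                   stars = stars_at(c(3, 6)))
  a <- zapper_policy(st, 1, cfg)
  expect_equal(a$kind, "move")
  expect_equal(a$dir, "right")
  # (ii) rival strictly closer to my nearest star, sharing my row: zap
  st2 <- grid_state(pos5(c(3, 3), c(3, 5), c(0, 0), c(9, 0), c(9, 9)),
                    stars = stars_at(c(3, 7)))
  a2 <- zapper_policy(st2, 1, cfg)
  expect_equal(a2$kind, "zap")
  expect_equal(a2$dir, "right")
  # (iii) rival closer but no shared line: move toward the star, never zap
  st3 <- grid_state(pos5(c(3, 3), c(4, 5), c(0, 0), c(9, 0), c(9, 9)),
                    stars = stars_at(c(5, 5)))
  a3 <- zapper_policy(st3, 1, cfg)
  expect_equal(a3$kind, "move")
  expect_equal(a3$dir, "down")  # row axis first
})

test_that("avoider policy moves away instead of zapping", {
  # same competition fixture as the zapper zap case: must move, never zap
  st <- grid_state(pos5(c(3, 3), c(3, 5), c(0, 0), c(9, 0), c(9, 9)),
                   stars = stars_at(c(3, 7)))
  a <- avoider_policy(st, 1, cfg)
  expect_equal(a$kind, "move")
  # no alternative star: the move must increase distance from the rival
  d0 <- sum(abs(st$pos[1, ] - st$pos[2, ]))
  land <- switch(a$dir, up = st$pos[1, ] + c(-1, 0), down = st$pos[1, ] + c(1, 0),
                 left = st$pos[1, ] + c(0, -1), right = st$pos[1, ] + c(0, 1))
  expect_gt(sum(abs(land - st$pos[2, ])), d0)
  # single star, self strictly closest: identical to the zapper policy
  st2 <- grid_state(pos5(c(3, 3), c(9, 9), c(0, 0), c(9, 0), c(0, 9)),
                    stars = stars_at(c(3, 6)))
  expect_equal(avoider_policy(st2, 1, cfg), zapper_policy(st2, 1, cfg))
})

test_that("games are deterministic given the seed and respect the record budget", {
  cfg0 <- game_config(n_turns = 50, seed = 7)
  log1 <- run_game(cfg0)
  log2 <- run_game(cfg0)
  expect_identical(log1, log2)
  expect_lte(nrow(log1), 50 * 5)
})

test_that("all-avoider games contain no zaps; all-zapper games zap across seeds", {
  zap_counts <- vapply(1:20, function(s) {
    cfg0 <- game_config(behavior_mix = "all_avoiders", n_turns = 40, seed = s,
                        players = default_players("groups", "all_avoiders",
                                                  participant_policy = "avoider"))
    sum(run_game(cfg0)$action == "zap")
  }, numeric(1))
  expect_true(all(zap_counts == 0))

  zap_counts <- vapply(1:20, function(s) {
    cfg0 <- game_config(behavior_mix = "all_zappers", n_turns = 100, seed = s,
                        n_stars_init = 2,
                        players = default_players("groups", "all_zappers",
                                                  participant_policy = "avoider"))
    sum(run_game(cfg0)$action == "zap")
  }, numeric(1))
  expect_gte(sum(zap_counts > 0), 19)
})

test_that("occupancy, scores and time-out absences are consistent over seeds", {
  for (s in 1:5) {
    log <- run_game(game_config(seed = 100 + s, n_turns = 60))
    # occupancy uniqueness at every recorded pre-move state
    for (i in seq_len(nrow(log))) {
      pos <- log$pos[[i]]
      act <- which(!is.na(pos[, 1]))
      cells <- pos[act, 1] * 100 + pos[act, 2]
      expect_equal(anyDuplicated(cells), 0)
    }
    # final scores equal the per-actor star_collected counts
    final <- attr(log, "final_state")
    tallies <- tapply(log$star_collected, log$actor, sum)
    for (pid in names(tallies)) {
      expect_equal(final$score[as.integer(pid)], unname(tallies[pid]))
    }
    # a zapped player emits no record for exactly timeout_turns rounds
    zaps <- which(log$action == "zap" & lengths(log$zapped) > 0)
    for (i in zaps) {
      for (v in log$zapped[[i]]) {
        r <- log$round[i]
        gap <- log$round[log$actor == v & log$round > r]
        absent <- setdiff((r + 1):(r + 3), gap)
        expect_equal(absent, (r + 1):(r + 3))
      }
    }
  }
})
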