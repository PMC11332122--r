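# Hand-built logs and brute-force recounts for the extraction tests.

pos5 <- function(...) {
  m <- matrix(as.integer(rbind(...)), ncol = 2)
  colnames(m) <- c("row", "col")
  m
}

stars_at <- function(...) {
  if (!...length()) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  m <- matrix(as.integer(rbind(...)), ncol = 2)
  colnames(m) <- c("row", "col")
  m
}

# assemble a stargrid_log from hand-written records
make_log <- function(records, config) {
  log <- tibble::tibble(
    round = vapply(records, function(r) as.integer(r$round), integer(1)),
    actor = vapply(records, function(r) as.integer(r$actor), integer(1)),
    action = vapply(records, function(r) r$action, character(1)),
    dir = vapply(records, function(r) r$dir %||% "up", character(1)),
    zapped = lapply(records, function(r) as.integer(r$zapped %||% integer(0))),
    star_collected = vapply(records, function(r) isTRUE(r$star_collected), logical(1)),
    pos = lapply(records, function(r) r$pos),
    timeout = lapply(records, function(r) as.integer(r$timeout %||% integer(config$n_players))),
    score = lapply(records, function(r) as.integer(r$score %||% integer(config$n_players))),
    stars = lapply(records, function(r) r$stars %||% stars_at())
  )
  attr(log, "config") <- config
  attr(log, "players") <- config$players
  class(log) <- c("stargrid_log", class(log))
  log
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent re-derivation of the zap/avoid/none classification from raw
# positions, used to cross-check classify_observed_action on random games
brute_classify <- function(pos, stars, actor, action, zapped) {
  if (action == "zap") {
    return(if (length(zapped) > 0) "zap" else "none")
  }
  others <- setdiff(which(!is.na(pos[, 1])), actor)
  can_zap <- FALSE
  for (o in others) {
    if (pos[o, 1] == pos[actor, 1] || pos[o, 2] == pos[actor, 2]) can_zap <- TRUE
  }
  if (!can_zap) return("none")
  if (nrow(stars) > 0) {
    for (s in seq_len(nrow(stars))) {
      mine <- abs(stars[s, 1] - pos[actor, 1]) + abs(stars[s, 2] - pos[actor, 2])
      closest <- TRUE
      for (o in others) {
        d <- abs(stars[s, 1] - pos[o, 1]) + abs(stars[s, 2] - pos[o, 2])
        if (d <= mine) closest <- FALSE
      }
      if (closest) return("none")
    }
  }
  "avoid"
}

# hand recount of per-target zap opportunities and zaps from a raw log
brute_zap_counts <- function(log, participant) {
  counts <- list()
  for (i in which(log$actor == participant)) {
    pos <- log$pos[[i]]
    others <- setdiff(which(!is.na(pos[, 1])), participant)
    for (o in others) {
      if (pos[o, 1] == pos[participant, 1] || pos[o, 2] == pos[participant, 2]) {
        key <- as.character(o)
        cur <- counts[[key]] %||% c(zap = 0L, opp = 0L)
        cur["opp"] <- cur["opp"] + 1L
        if (log$action[i] == "zap" && o %in% log$zapped[[i]]) {
          cur["zap"] <- cur["zap"] + 1L
        }
        counts[[key]] <- cur
      }
    }
  }
  counts
}
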