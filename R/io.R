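#' @title Game-log file format
#' @description Game logs are serialised as JSON Lines: a header line with
#'   the game configuration and roster, then one line per turn record.
#'   Coordinates are 0-based `(row, col)` with the origin at the top left;
#'   a `null` position marks a player in the time-out zone.
#' @name log_io
NULL

#' Write a game log as JSON Lines
#'
#' @param log A `stargrid_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_game_log <- function(log, path) {
  config <- attr(log, "config")
  players <- attr(log, "players")
  header <- list(type = "config",
                 config = config[setdiff(names(config), "players")],
                 players = players)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(log))) {
    pos <- log$pos[[i]]
    pos_list <- lapply(seq_len(nrow(pos)), function(r) {
      if (is.na(pos[r, 1])) NULL else unname(pos[r, ])
    })
    rec <- list(
      type = "turn", round = log$round[i], actor = log$actor[i],
      action = log$action[i], dir = log$dir[i],
      zapped = as.integer(log$zapped[[i]]),
      star_collected = log$star_collected[i],
      pos = pos_list,
      timeout = as.integer(log$timeout[[i]]),
      score = as.integer(log$score[[i]]),
      stars = apply(log$stars[[i]], 1, function(s) unname(s), simplify = FALSE)
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a game log written by [write_game_log()]
#'
#' @param path File path.
#' @return A `stargrid_log` tibble.
#' @export
read_game_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$type, "config")) stop("missing config header line")
  players <- tibble::as_tibble(header$players)
  cfg_args <- header$config
  cfg_args$turn_order <- as.integer(cfg_args$turn_order)
  config <- do.call(game_config, c(cfg_args, list(players = players)))

  recs <- lapply(lines[-1], jsonlite::fromJSON, simplifyVector = FALSE)
  n <- length(recs)
  as_pos <- function(lst, np) {
    m <- matrix(NA_integer_, np, 2, dimnames = list(NULL, c("row", "col")))
    for (r in seq_len(np)) {
      if (!is.null(lst[[r]])) m[r, ] <- as.integer(unlist(lst[[r]]))
    }
    m
  }
  as_stars <- function(lst) {
    if (!length(lst)) return(no_stars())
    m <- do.call(rbind, lapply(lst, function(s) as.integer(unlist(s))))
    dimnames(m) <- list(NULL, c("row", "col"))
    m
  }
  np <- config$n_players
  log <- tibble::tibble(
    round = vapply(recs, function(r) as.integer(r$round), integer(1)),
    actor = vapply(recs, function(r) as.integer(r$actor), integer(1)),
    action = vapply(recs, function(r) r$action, character(1)),
    dir = vapply(recs, function(r) r$dir, character(1)),
    zapped = lapply(recs, function(r) as.integer(unlist(r$zapped))),
    star_collected = vapply(recs, function(r) isTRUE(r$star_collected), logical(1)),
    pos = lapply(recs, function(r) as_pos(r$pos, np)),
    timeout = lapply(recs, function(r) as.integer(unlist(r$timeout))),
    score = lapply(recs, function(r) as.integer(unlist(r$score))),
    stars = lapply(recs, function(r) as_stars(r$stars))
  )
  attr(log, "config") <- config
  attr(log, "players") <- players
  class(log) <- c("stargrid_log", class(log))
  log
}
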