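#' Game configuration
#'
#' Session-level timing and structure: eight 90-second practice rounds whose
#' outcomes do not feed the winning ledger, then 30-second main rounds with
#' 2 seconds of feedback each, until the winning condition fires or the
#' 60-minute clock runs out at a round boundary (a round in progress at the
#' hour mark completes). Simulated response latency is lognormal,
#' truncated at the round cap; the 1-second hold-to-send dwell is treated as
#' part of that latency.
#'
#' @param condition One of [conditions()].
#' @param n_practice Number of practice rounds.
#' @param practice_cap_s,round_cap_s Response-time caps (seconds) for
#'   practice and main rounds.
#' @param feedback_s Feedback duration appended to every round.
#' @param session_s Total session budget in seconds.
#' @param latency_meanlog,latency_sdlog Lognormal latency parameters.
#' @return A `game_config` list.
#' @export
game_config <- function(condition, n_practice = 8, practice_cap_s = 90,
                        round_cap_s = 30, feedback_s = 2, session_s = 3600,
                        latency_meanlog = log(8), latency_sdlog = 0.5) {
  condition <- match.arg(condition, conditions())
  stopifnot(n_practice >= 0, practice_cap_s > 0, round_cap_s > 0,
            feedback_s >= 0, session_s > 0)
  structure(list(condition = condition, n_practice = n_practice,
                 practice_cap_s = practice_cap_s, round_cap_s = round_cap_s,
                 feedback_s = feedback_s, session_s = session_s,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog),
            class = "game_config")
}

new_game_log <- function(dyad_id, condition, rounds, won) {
  structure(list(dyad_id = dyad_id, condition = condition,
                 rounds = rounds, won = won,
                 total_time_s = sum(rounds$duration_s)),
            class = "game_log")
}

#' @export
print.game_log <- function(x, ...) {
  cat(sprintf("<game_log %s | %s | %d rounds (%d practice) | %s | %.0f s>\n",
              x$dyad_id, x$condition, nrow(x$rounds),
              sum(x$rounds$is_practice),
              if (x$won) "won" else "not won", x$total_time_s))
  invisible(x)
}

#' Simulate one dyad's full session
#'
#' Plays the practice rounds and then main rounds between a sender and a
#' receiver agent. Each round: a target is drawn uniformly at random, the
#' sender produces a pad point, views are rendered per condition and role,
#' the receiver guesses, and both agents receive feedback (the receiver
#' stores an exemplar of what it saw against the revealed target). Main-round
#' outcomes update the reliable-signal ledger; after every correct guess the
#' winning condition is checked and, if met, the game ends immediately. The
#' session otherwise ends at the first round boundary at or past
#' `session_s` cumulative seconds (practice time included). Fully
#' reproducible given `seed`.
#'
#' @param config A [game_config()].
#' @param sender A [sender_new()] state.
#' @param receiver A [receiver_new()] state.
#' @param seed Integer seed for this game's random stream.
#' @param dyad_id Identifier recorded in the log.
#' @return A `game_log`: `dyad_id`, `condition`, `won`, `total_time_s`, and
#'   a `rounds` tibble with columns `round_index`, `is_practice`, `target`,
#'   `sent_u`, `sent_v`, `guess`, `correct`, `duration_s`.
#' @export
run_game <- function(config, sender, receiver, seed, dyad_id = "dyad_01") {
  stopifnot(inherits(config, "game_config"))
  custom_sender <- !inherits(sender, "sender_state")
  custom_receiver <- !inherits(receiver, "receiver_state")
  if (custom_sender && !is.function(sender$produce_fn)) {
    stop("sender must be a sender_state or a list with a produce_fn")
  }
  if (custom_receiver && (!is.function(receiver$guess_fn) ||
                          !is.function(receiver$learn_fn))) {
    stop("receiver must be a receiver_state or a list with guess_fn/learn_fn")
  }
  set.seed(as.integer(seed))
  refs <- referents()
  cond <- config$condition
  s_color <- sees_color(cond, "sender")
  r_color <- sees_color(cond, "receiver")

  cap <- config$n_practice +
    ceiling(config$session_s / max(config$feedback_s, 0.5)) + 8
  target <- character(cap); guess <- character(cap)
  su <- numeric(cap); sv <- numeric(cap)
  correct <- logical(cap); dur <- numeric(cap); practice <- logical(cap)

  ledger <- ledger_new(refs)
  t_cum <- 0
  i <- 0L
  won <- FALSE
  repeat {
    is_prac <- i < config$n_practice
    if (!is_prac && t_cum >= config$session_s) break
    i <- i + 1L
    tgt <- sample(refs, 1)
    prod <- if (custom_sender) sender$produce_fn(sender, tgt, s_color) else
      produce_point(sender, tgt, s_color)
    sender <- prod$state
    pt <- prod$point
    rview <- render_view(cond, "receiver", pt[["u"]], pt[["v"]])
    if (custom_receiver) {
      g <- receiver$guess_fn(receiver, rview, tgt)$guess
      receiver <- receiver$learn_fn(receiver, rview, tgt)
    } else {
      g <- receiver_guess(receiver, rview)$guess
      receiver <- receiver_learn(receiver, rview, tgt)
    }
    ok <- identical(g, tgt)
    cap_s <- if (is_prac) config$practice_cap_s else config$round_cap_s
    latency <- min(stats::rlnorm(1, config$latency_meanlog,
                                 config$latency_sdlog), cap_s)
    target[i] <- tgt; guess[i] <- g; su[i] <- pt[["u"]]; sv[i] <- pt[["v"]]
    correct[i] <- ok; dur[i] <- latency + config$feedback_s
    practice[i] <- is_prac
    t_cum <- t_cum + dur[i]
    if (!is_prac) {
      ledger <- ledger_update(ledger, tgt, ok)
      if (ok && winning_condition_met(ledger)) {
        won <- TRUE
        break
      }
    }
  }
  rounds <- tibble::tibble(
    round_index = seq_len(i), is_practice = practice[seq_len(i)],
    target = target[seq_len(i)], sent_u = su[seq_len(i)],
    sent_v = sv[seq_len(i)], guess = guess[seq_len(i)],
    correct = correct[seq_len(i)], duration_s = dur[seq_len(i)]
  )
  new_game_log(dyad_id, cond, rounds, won)
}

#' Build a fixed signal bank for receiver-only sessions
#'
#' Draws three anchored productions per referent from a color-seeing sender,
#' mimicking the harvesting of a small set of real signals (with their
#' production noise) from a single color-condition game.
#'
#' @param params A [sender_params()].
#' @param seed Integer seed.
#' @return A tibble of 18 rows: `referent`, `u`, `v`.
#' @export
make_signal_bank <- function(params = sender_params(), seed = 1) {
  set.seed(as.integer(seed))
  sender <- sender_new(params)
  rows <- lapply(referents(), function(r) {
    pts <- t(vapply(1:3, function(k) {
      res <- produce_point(sender, r, sees_color = TRUE)
      res$point
    }, numeric(2)))
    tibble::tibble(referent = r, u = pts[, 1], v = pts[, 2])
  })
  do.call(rbind, rows)
}

#' Simulate a receiver-only session with fixed signals
#'
#' The single-player follow-up paradigm: no sender; each round one of 18
#' pre-recorded signals (three per referent) is drawn at random and shown as
#' a color or a dot, the participant guesses, and feedback names the correct
#' referent. With `log_panel = TRUE`, four pre-selected referents get the
#' first signal shown for them pinned to a persistent on-screen log after
#' that round; the log is never updated afterwards. The session runs for
#' `duration_s` seconds (15 minutes by default).
#'
#' @param receiver A [receiver_new()] state.
#' @param signal_bank A [make_signal_bank()] tibble: exactly 18 rows, three
#'   per referent.
#' @param signal_type `"color"` or `"dot"`: what the participant sees.
#' @param log_panel Is the persistent signal log present?
#' @param log_panel_size Number of pre-selected logged referents.
#' @param duration_s Session length in seconds.
#' @param seed Integer seed.
#' @param participant_id Identifier recorded in the log.
#' @param latency_meanlog,latency_sdlog Lognormal response-latency
#'   parameters; responses are capped at 30 s with 2 s feedback.
#' @return A `game_log` (no practice rounds, `won = FALSE`) with attributes
#'   `signal_type`, `log_panel`, and `log_contents` (tibble of pinned
#'   signals, in pinning order).
#' @export
run_receiver_only_session <- function(receiver, signal_bank,
                                      signal_type = c("color", "dot"),
                                      log_panel = FALSE, log_panel_size = 4,
                                      duration_s = 900, seed = 1,
                                      participant_id = "p01",
                                      latency_meanlog = log(6),
                                      latency_sdlog = 0.5) {
  signal_type <- match.arg(signal_type)
  stopifnot(inherits(receiver, "receiver_state"))
  if (!is.data.frame(signal_bank) || nrow(signal_bank) != 18 ||
      !all(table(signal_bank$referent) == 3) ||
      !all(signal_bank$referent %in% referents())) {
    stop("signal_bank must hold exactly 18 signals, three per referent")
  }
  assert_pad(signal_bank$u, signal_bank$v)
  set.seed(as.integer(seed))
  logged_refs <- if (log_panel) sample(referents(), log_panel_size) else
    character(0)
  pending <- logged_refs
  log_rows <- list()
  cond_view <- if (signal_type == "color") "high" else "low"

  n_cap <- ceiling(duration_s / 2) + 2
  target <- character(n_cap); guess <- character(n_cap)
  su <- numeric(n_cap); sv <- numeric(n_cap)
  correct <- logical(n_cap); dur <- numeric(n_cap)
  t_cum <- 0; i <- 0L
  while (t_cum < duration_s) {
    i <- i + 1L
    k <- sample.int(18, 1)
    tgt <- signal_bank$referent[k]
    u <- signal_bank$u[k]; v <- signal_bank$v[k]
    view <- render_view(cond_view, "receiver", u, v)
    g <- receiver_guess(receiver, view)$guess
    receiver <- receiver_learn(receiver, view, tgt)
    if (tgt %in% pending) {
      receiver <- receiver_learn(receiver, view, tgt, pin = TRUE)
      log_rows[[length(log_rows) + 1]] <-
        tibble::tibble(referent = tgt, u = u, v = v, round_index = i)
      pending <- setdiff(pending, tgt)
    }
    target[i] <- tgt; guess[i] <- g; su[i] <- u; sv[i] <- v
    correct[i] <- identical(g, tgt)
    dur[i] <- min(stats::rlnorm(1, latency_meanlog, latency_sdlog), 30) + 2
    t_cum <- t_cum + dur[i]
  }
  rounds <- tibble::tibble(
    round_index = seq_len(i), is_practice = FALSE,
    target = target[seq_len(i)], sent_u = su[seq_len(i)],
    sent_v = sv[seq_len(i)], guess = guess[seq_len(i)],
    correct = correct[seq_len(i)], duration_s = dur[seq_len(i)]
  )
  log <- new_game_log(participant_id,
                      paste0("followup_", signal_type,
                             if (log_panel) "_log" else "_nolog"),
                      rounds, won = FALSE)
  attr(log, "signal_type") <- signal_type
  attr(log, "log_panel") <- log_panel
  attr(log, "log_contents") <- if (length(log_rows)) do.call(rbind, log_rows)
    else tibble::tibble(referent = character(0), u = numeric(0),
                        v = numeric(0), round_index = integer(0))
  log
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483629)
}

#' Generate a synthetic cohort of dyads
#'
#' Runs [run_game()] for `n_per_condition` dyads in each condition with
#' per-dyad seeds derived from one master seed, so a cohort is reproducible
#' bit for bit. The default sizes match a cohort of 68 dyads (22 high, 22
#' low, 24 one-sided).
#'
#' @param n_per_condition Named integer vector over [conditions()].
#' @param sender_params,receiver_params Agent parameters shared by all dyads.
#' @param seed Master integer seed.
#' @param config_fn Function `condition -> game_config`, for overriding
#'   timing settings.
#' @return A list of `game_log` objects.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(c(high = 2, low = 2, one_sided = 2), seed = 7)
#' sapply(cohort, function(g) g$condition)
#' }
generate_cohort <- function(n_per_condition = c(high = 22, low = 22,
                                                one_sided = 24),
                            sender_params = refgame::sender_params(),
                            receiver_params = refgame::receiver_params(),
                            seed = 1,
                            config_fn = game_config) {
  stopifnot(all(names(n_per_condition) %in% conditions()),
            all(n_per_condition >= 1))
  logs <- list()
  idx <- 0L
  for (cond in names(n_per_condition)) {
    cfg <- config_fn(cond)
    for (j in seq_len(n_per_condition[[cond]])) {
      idx <- idx + 1L
      logs[[idx]] <- run_game(
        cfg, sender_new(sender_params), receiver_new(receiver_params),
        seed = derive_seed(seed, idx),
        dyad_id = sprintf("%s_%02d", cond, j)
      )
    }
  }
  logs
}
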