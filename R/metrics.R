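check_log <- function(log) {
  if (!inherits(log, "game_log")) stop("expected a game_log object")
  if (nrow(log$rounds) == 0) stop("log has no rounds")
  invisible(TRUE)
}

#' Per-round count of established signals
#'
#' For every round in scope, the number of referents whose guess-outcome
#' history up to and including that round satisfies the 3-of-the-last-4
#' criterion (see [referent_established()]). With
#' `include_practice = TRUE` practice rounds are both scored and counted in
#' the histories, matching the success-index convention; with `FALSE` the
#' series covers main rounds only and histories start at the first main
#' round, matching the in-game ledger.
#'
#' @param log A `game_log`.
#' @param include_practice Include practice rounds in scope and histories?
#' @return A tibble with `round_index`, `is_practice`, and `s` (0..6).
#' @export
established_series <- function(log, include_practice = TRUE) {
  check_log(log)
  r <- log$rounds
  if (!include_practice) r <- r[!r$is_practice, , drop = FALSE]
  if (nrow(r) == 0) stop("no rounds in scope")
  refs <- referents()
  hist <- stats::setNames(vector("list", length(refs)), refs)
  for (k in refs) hist[[k]] <- logical(0)
  est <- stats::setNames(logical(length(refs)), refs)
  s <- integer(nrow(r))
  for (t in seq_len(nrow(r))) {
    tgt <- r$target[t]
    h <- c(hist[[tgt]], r$correct[t])
    hist[[tgt]] <- h
    n <- length(h)
    est[tgt] <- n >= 4L && sum(h[(n - 3L):n]) >= 3L
    s[t] <- sum(est)
  }
  tibble::tibble(round_index = r$round_index, is_practice = r$is_practice,
                 s = s)
}

#' Estimated extra rounds for a won game
#'
#' Dyads that trigger the winning condition stop early; to compare their
#' success index with dyads that played the full hour, the index is padded
#' with "dummy rounds" in which all six referents count as established. The
#' number of dummy rounds is the remaining session time divided by the mean
#' duration of the game's final four rounds, rounded down (a dyad cannot
#' play a partial round).
#'
#' @param log A `game_log`.
#' @param session_s Full session length in seconds.
#' @return Non-negative integer; 0 for games that were not won.
#' @export
dummy_round_count <- function(log, session_s = 3600) {
  check_log(log)
  if (!isTRUE(log$won)) return(0L)
  if (nrow(log$rounds) < 4) stop("log must have at least 4 rounds")
  d <- log$rounds$duration_s
  m <- mean(d[(length(d) - 3L):length(d)])
  if (!is.finite(m) || m <= 0) stop("non-positive mean round duration")
  remaining <- max(session_s - log$total_time_s, 0)
  as.integer(floor(remaining / m))
}

#' Success index from an established-count series
#'
#' The bare formula behind [success_index()]:
#' `(sum(s) + 6 * n_dummy) / (6 * (length(s) + n_dummy))`. Useful when the
#' per-round established counts are already in hand.
#'
#' @param s Integer vector of per-round established counts, each in 0..6.
#' @param n_dummy Number of fully established dummy rounds to append.
#' @return The index, a number in `[0, 1]`.
#' @export
#' @examples
#' success_index_from_series(c(0, 0, 0, 1, 1, 2, 3, 4, 5, 6))  # 22/60
success_index_from_series <- function(s, n_dummy = 0L) {
  stopifnot(length(s) + n_dummy >= 1, all(s >= 0), all(s <= 6), n_dummy >= 0)
  (sum(s) + 6 * n_dummy) / (6 * (length(s) + n_dummy))
}

#' Dyadic success index
#'
#' The scalar summary of how many referents a dyad reliably signaled and how
#' fast: the cumulative established count summed over rounds, divided by
#' 6 times the number of rounds, `sum(s_t) / (6 * n_r)`. It rewards both
#' reaching many established signals and reaching them early, and is
#' strictly below 1 because no referent can be established before its fourth
#' occurrence. By default practice rounds are included and won games are
#' padded with fully established dummy rounds (see [dummy_round_count()]);
#' both choices can be toggled for sensitivity variants.
#'
#' @param log A `game_log`.
#' @param include_practice Include practice rounds?
#' @param include_dummy Pad won games with dummy rounds?
#' @param session_s Full session length for the dummy extrapolation.
#' @return A `success_index_result`: `index`, `n_rounds_used` (real rounds
#'   scored), `n_dummy`, and the flags.
#' @export
#' @examples
#' \donttest{
#' g <- run_game(game_config("high"), sender_new(), receiver_new(), seed = 1)
#' success_index(g)$index
#' }
success_index <- function(log, include_practice = TRUE, include_dummy = TRUE,
                          session_s = 3600) {
  es <- established_series(log, include_practice = include_practice)
  n_dummy <- if (include_dummy) dummy_round_count(log, session_s) else 0L
  n_used <- nrow(es)
  idx <- success_index_from_series(es$s, n_dummy)
  structure(list(index = idx, n_rounds_used = n_used, n_dummy = n_dummy,
                 include_practice = include_practice,
                 include_dummy = include_dummy),
            class = "success_index_result")
}

#' @export
print.success_index_result <- function(x, ...) {
  cat(sprintf(
    "<success_index %.4f | %d rounds + %d dummy | practice %s, dummy %s>\n",
    x$index, x$n_rounds_used, x$n_dummy,
    if (x$include_practice) "in" else "out",
    if (x$include_dummy) "in" else "out"))
  invisible(x)
}

#' Signal stability observations
#'
#' Production stability is measured as the Euclidean distance (in normalized
#' pad units) between a signal's pad point and the previous signal's pad
#' point for the same referent, within a dyad. The first signal for each
#' referent yields no observation; rounds without a sent signal are skipped.
#' Lower distances mean the sender hit the same spot more consistently.
#'
#' @param logs A `game_log` or list of them.
#' @param include_practice Include practice rounds?
#' @param which_send If a round carries several sends (possible in external
#'   data collapsed to one row per send), `"last"` keeps the send the guess
#'   responded to; `"first"` keeps the earliest.
#' @return A tibble: `dyad_id`, `condition`, `referent`, `round_index`,
#'   `distance`.
#' @export
stability_observations <- function(logs, include_practice = TRUE,
                                   which_send = c("last", "first")) {
  which_send <- match.arg(which_send)
  if (inherits(logs, "game_log")) logs <- list(logs)
  out <- lapply(logs, function(log) {
    check_log(log)
    r <- log$rounds
    if (!include_practice) r <- r[!r$is_practice, , drop = FALSE]
    r <- r[!is.na(r$sent_u) & !is.na(r$sent_v), , drop = FALSE]
    if (anyDuplicated(r$round_index)) {
      keep <- if (which_send == "last") !duplicated(r$round_index,
                                                    fromLast = TRUE)
              else !duplicated(r$round_index)
      r <- r[keep, , drop = FALSE]
    }
    if (nrow(r) < 2) return(NULL)
    res <- lapply(unique(r$target), function(ref) {
      rr <- r[r$target == ref, , drop = FALSE]
      if (nrow(rr) < 2) return(NULL)
      n <- nrow(rr)
      tibble::tibble(
        dyad_id = log$dyad_id, condition = log$condition, referent = ref,
        round_index = rr$round_index[-1],
        distance = sqrt(diff(rr$sent_u)^2 + diff(rr$sent_v)^2)
      )
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- tibble::tibble(dyad_id = character(0), condition = character(0),
                          referent = character(0), round_index = integer(0),
                          distance = numeric(0))
  }
  out
}

#' Receiver guessing accuracy
#'
#' Fraction of rounds in scope with a correct guess; timeouts (no guess)
#' count as incorrect.
#'
#' @param log A `game_log`.
#' @param scope `"main_only"` (default, the rounds that count toward the
#'   game) or `"all"`.
#' @return Numeric in `[0, 1]`.
#' @export
accuracy <- function(log, scope = c("main_only", "all")) {
  scope <- match.arg(scope)
  check_log(log)
  r <- log$rounds
  if (scope == "main_only") r <- r[!r$is_practice, , drop = FALSE]
  if (nrow(r) == 0) stop("no rounds in scope")
  mean(r$correct)
}

#' Distribution of established-set sizes by condition
#'
#' For each condition, the proportion of rounds (pooled over its dyads)
#' spent with each number of established signals, 0 through 6. Practice
#' rounds are included by default; dummy rounds never are.
#'
#' @param logs List of `game_log` objects.
#' @param include_practice Include practice rounds?
#' @return A tibble: `condition`, `set_size` (0..6), `prop`; proportions sum
#'   to 1 within condition.
#' @export
signal_set_proportions <- function(logs, include_practice = TRUE) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  stopifnot(length(logs) >= 1)
  conds <- unique(vapply(logs, function(g) g$condition, character(1)))
  res <- lapply(conds, function(cond) {
    s_all <- unlist(lapply(logs[vapply(logs, function(g)
      g$condition == cond, logical(1))], function(g) {
        established_series(g, include_practice = include_practice)$s
      }))
    counts <- tabulate(s_all + 1L, nbins = 7L)
    tibble::tibble(condition = cond, set_size = 0:6,
                   prop = counts / sum(counts))
  })
  do.call(rbind, res)
}

#' Total time and round count
#'
#' @param log A `game_log`.
#' @return List with `total_time_s` and `n_rounds` (practice + main).
#' @export
time_taken <- function(log) {
  check_log(log)
  list(total_time_s = log$total_time_s, n_rounds = nrow(log$rounds))
}

#' Per-dyad summary table
#'
#' One row per dyad with the dyad-level dependent variables used in the
#' condition contrasts: the default success index (practice and dummy rounds
#' included), its two sensitivity variants, receiver accuracy over main
#' rounds, game length, round count, and whether the game was won.
#'
#' @param logs List of `game_log` objects.
#' @param session_s Session length for the dummy extrapolation.
#' @return A tibble keyed by `dyad_id`.
#' @export
per_dyad_summary <- function(logs, session_s = 3600) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  rows <- lapply(logs, function(g) {
    tibble::tibble(
      dyad_id = g$dyad_id,
      condition = g$condition,
      success_index = success_index(g, TRUE, TRUE, session_s)$index,
      success_index_no_practice = success_index(g, FALSE, TRUE,
                                                session_s)$index,
      success_index_no_dummy = success_index(g, TRUE, FALSE)$index,
      accuracy = accuracy(g, "main_only"),
      game_length_s = g$total_time_s,
      n_rounds = nrow(g$rounds),
      won = g$won
    )
  })
  do.call(rbind, rows)
}

#' Round-level table for the round-by-round models
#'
#' One row per round per dyad with the established count `s`, its presence
#' indicator `1(s > 0)`, and the round number both raw (within dyad) and
#' z-scored across the pooled table (the scaling used by the round-by-round
#' mixed models). Dummy rounds are never included.
#'
#' @param logs List of `game_log` objects.
#' @param include_practice Include practice rounds?
#' @return A tibble: `dyad_id`, `condition`, `round_number`, `round_z`, `s`,
#'   `presence`.
#' @export
round_table <- function(logs, include_practice = TRUE) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  rows <- lapply(logs, function(g) {
    es <- established_series(g, include_practice = include_practice)
    tibble::tibble(
      dyad_id = g$dyad_id, condition = g$condition,
      round_number = seq_len(nrow(es)), s = es$s,
      presence = as.integer(es$s > 0)
    )
  })
  out <- do.call(rbind, rows)
  out$round_z <- as.numeric(scale(out$round_number))
  out[, c("dyad_id", "condition", "round_number", "round_z", "s",
          "presence")]
}
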