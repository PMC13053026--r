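#' Create an empty reliable-signal ledger
#'
#' The ledger keeps, per referent, the ordered history of guess outcomes
#' (most recent last) for rounds in which that referent was the target. It
#' backs both the in-game winning condition and the success-index metric.
#'
#' @param refs Referent labels the ledger tracks.
#' @return An object of class `reliable_ledger`.
#' @export
ledger_new <- function(refs = referents()) {
  l <- stats::setNames(vector("list", length(refs)), refs)
  for (r in refs) l[[r]] <- logical(0)
  structure(list(history = l), class = "reliable_ledger")
}

#' Append an outcome to the ledger
#'
#' @param ledger A [ledger_new()] object.
#' @param referent The round's target referent.
#' @param correct Logical: was the guess correct? A receiver timeout is
#'   recorded as `FALSE`.
#' @return The updated ledger.
#' @export
ledger_update <- function(ledger, referent, correct) {
  if (!referent %in% names(ledger$history)) {
    stop("unknown referent: ", referent)
  }
  ledger$history[[referent]] <- c(ledger$history[[referent]], isTRUE(correct))
  ledger
}

#' Is a referent's signal currently established?
#'
#' A referent counts as reliably established when it has been the target on
#' at least four occasions and at least three of the four most recent guesses
#' for it were correct (the 75%-over-the-last-four criterion). Referents with
#' fewer than four occasions are never established, so no dyad can start a
#' game with signals in place.
#'
#' @inheritParams ledger_update
#' @param referent Referent to query.
#' @return Logical scalar.
#' @export
#' @examples
#' l <- ledger_new()
#' for (ok in c(TRUE, TRUE, FALSE, TRUE)) l <- ledger_update(l, "banana", ok)
#' referent_established(l, "banana")  # TRUE: 3 of the last 4 correct
referent_established <- function(ledger, referent) {
  if (!referent %in% names(ledger$history)) {
    stop("unknown referent: ", referent)
  }
  h <- ledger$history[[referent]]
  n <- length(h)
  n >= 4L && sum(h[(n - 3L):n]) >= 3L
}

#' Count currently established referents
#'
#' @inheritParams ledger_update
#' @return Integer in `0..6`.
#' @export
ledger_established_count <- function(ledger) {
  sum(vapply(names(ledger$history), function(r) referent_established(ledger, r),
             logical(1)))
}

#' Has the winning condition been met?
#'
#' True when every referent is simultaneously established. In the engine this
#' is evaluated only immediately after a correct guess, which is the only
#' event that can newly satisfy it.
#'
#' @inheritParams ledger_update
#' @return Logical scalar.
#' @export
winning_condition_met <- function(ledger) {
  for (r in names(ledger$history)) {
    if (!referent_established(ledger, r)) return(FALSE)
  }
  TRUE
}
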