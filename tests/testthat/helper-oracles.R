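# Independent re-scan oracle for the established-count series: for every
# round t and referent r, re-derive establishment from the full prefix of
# the outcome sequence using occurrence counts, with no shared state with
# the package's sequential ledger.
oracle_established_series <- function(targets, correct) {
  refs <- referents()
  occ <- lapply(refs, function(r) which(targets == r))
  names(occ) <- refs
  flags <- lapply(refs, function(r) correct[occ[[r]]])
  names(flags) <- refs
  vapply(seq_along(targets), function(t) {
    sum(vapply(refs, function(r) {
      n <- findInterval(t, occ[[r]])
      n >= 4L && sum(flags[[r]][(n - 3L):n]) >= 3L
    }, logical(1)))
  }, integer(1))
}

# Build a game log directly from outcome sequences (no engine), with
# guesses made consistent with the correct flags.
make_outcome_log <- function(targets, correct, is_practice = NULL,
                             duration_s = NULL, won = FALSE,
                             dyad_id = "t01", condition = "low",
                             sent = NULL) {
  n <- length(targets)
  refs <- referents()
  if (is.null(is_practice)) is_practice <- rep(FALSE, n)
  if (is.null(duration_s)) duration_s <- rep(10, n)
  guess <- ifelse(correct, targets,
                  vapply(targets, function(tg) sample(setdiff(refs, tg), 1),
                         character(1)))
  if (is.null(sent)) sent <- matrix(0.5, n, 2)
  rounds <- tibble::tibble(
    round_index = seq_len(n), is_practice = is_practice, target = targets,
    sent_u = sent[, 1], sent_v = sent[, 2], guess = guess,
    correct = correct, duration_s = duration_s)
  refgame:::new_game_log(dyad_id, condition, rounds, won)
}

random_outcome_log <- function(n, p_correct = 0.5, ...) {
  targets <- sample(referents(), n, replace = TRUE)
  make_outcome_log(targets, stats::runif(n) < p_correct, ...)
}

# Reference CIELAB (D65, 2 deg) -> sRGB transform, written out from the
# standard definition, as an independent check on the display conversion.
ref_lab_to_srgb <- function(L, a, b) {
  wp <- c(X = 0.95047, Y = 1, Z = 1.08883)
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t^3 > 216 / 24389, t^3,
                             (116 * t - 16) * 27 / 24389)
  xyz <- c(wp[1] * finv(fx), wp[2] * finv(fy), wp[3] * finv(fz))
  m <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                -0.9692660, 1.8760108, 0.0415560,
                0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)
  lin <- as.numeric(m %*% xyz)
  gam <- ifelse(lin <= 0.0031308, 12.92 * lin,
                1.055 * lin^(1 / 2.4) - 0.055)
  pmin(pmax(gam, 0), 1)
}

# A receiver that always guesses the true target (sees it via the engine's
# custom-agent hook), and one that always guesses a fixed referent.
oracle_receiver <- function() {
  list(guess_fn = function(state, view, target) list(guess = target),
       learn_fn = function(state, view, target) state)
}
fixed_receiver <- function(ref = "banana") {
  list(guess_fn = function(state, view, target) list(guess = ref),
       learn_fn = function(state, view, target) state)
}
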