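#' Default iconic anchor positions
#'
#' Pad positions whose colors match the population color association of each
#' referent: yellow for banana, red for strawberry, orange-red for orange,
#' green for kiwi, dark blue for blueberry, dark purple for eggplant. The
#' anchors are well separated in the unit square (minimum pairwise distance
#' about 0.2) and sit where the colorspace geometry produces the intended
#' hue. They are overridable wherever agent parameters are accepted.
#'
#' @return A 6 x 2 matrix with rows named by referent and columns `u`, `v`.
#' @export
default_anchors <- function() {
  m <- rbind(
    banana     = c(0.50, 0.04),
    eggplant   = c(0.12, 0.88),
    strawberry = c(0.02, 0.10),
    blueberry  = c(0.50, 0.97),
    orange     = c(0.20, 0.02),
    kiwi       = c(0.95, 0.35)
  )
  colnames(m) <- c("u", "v")
  m
}

#' Sender agent parameters
#'
#' The sender model has two production modes. When the sender sees colors,
#' each referent's production is anchored: a draw from an isotropic Gaussian
#' around the referent's iconic anchor with motor noise `sigma_motor`
#' (iconicity constrains form, so productions stay near the anchor). When
#' the sender sees only a dot, there is no anchor; the sender maintains an
#' arbitrary convention point per referent that drifts by `sigma_drift` at
#' every reuse and, with probability `p_forget`, is forgotten and resampled
#' uniformly over the pad — the instability expected of unanchored
#' conventions.
#'
#' @param sigma_motor SD of 2-D Gaussian motor noise, in pad units.
#' @param sigma_drift Per-reuse drift SD of arbitrary conventions, pad units.
#' @param p_forget Probability a convention is forgotten and resampled.
#' @param anchors Referent-by-`(u, v)` matrix of iconic anchors.
#' @return A `sender_params` list.
#' @export
sender_params <- function(sigma_motor = 0.03, sigma_drift = 0.15,
                          p_forget = 0.25, anchors = default_anchors()) {
  stopifnot(sigma_motor >= 0, sigma_drift >= 0,
            p_forget >= 0, p_forget <= 1)
  if (!all(referents() %in% rownames(anchors))) {
    stop("anchors must cover all six referents")
  }
  if (min(stats::dist(anchors)) <= 0) stop("anchors must be distinct")
  structure(list(sigma_motor = sigma_motor, sigma_drift = sigma_drift,
                 p_forget = p_forget, anchors = anchors),
            class = "sender_params")
}

#' Create sender agent state
#'
#' @param params A [sender_params()] object.
#' @return Mutable-by-return sender state: parameters plus the current
#'   arbitrary convention point per referent (lazily initialized).
#' @export
sender_new <- function(params = sender_params()) {
  structure(list(params = params,
                 conventions = stats::setNames(
                   vector("list", length(referents())), referents())),
            class = "sender_state")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Produce a pad point for a referent
#'
#' One production step of the sender model; see [sender_params()] for the
#' two modes. Draws are clamped to the unit square.
#'
#' @param state A [sender_new()] state.
#' @param referent Target referent.
#' @param sees_color Does the sender see colors (anchored mode)?
#' @return List with `point` (named `u`, `v`) and the updated `state`.
#' @export
produce_point <- function(state, referent, sees_color) {
  p <- state$params
  if (!referent %in% rownames(p$anchors)) stop("unknown referent: ", referent)
  if (sees_color) {
    pt <- p$anchors[referent, ] + stats::rnorm(2, 0, p$sigma_motor)
  } else {
    conv <- state$conventions[[referent]]
    if (is.null(conv) || stats::runif(1) < p$p_forget) {
      conv <- stats::runif(2)
    } else {
      conv <- clamp01(conv + stats::rnorm(2, 0, p$sigma_drift))
    }
    state$conventions[[referent]] <- conv
    pt <- conv + stats::rnorm(2, 0, p$sigma_motor)
  }
  pt <- clamp01(pt)
  names(pt) <- c("u", "v")
  list(point = pt, state = state)
}

#' Receiver agent parameters
#'
#' The receiver classifies each incoming signal by a mixture of exemplar
#' memory and, for color signals only, an iconic prior. Exemplar memory
#' stores up to `memory_capacity` recent `(signal, referent)` pairs per
#' referent, and scores a candidate referent by the best Gaussian-kernel
#' similarity between the viewed signal and its stored exemplars. The iconic
#' prior scores a candidate by the Lab-space similarity of the viewed color
#' to the candidate's anchor color, weighted by `lambda_prior`; it is forced
#' to zero for dot views, where no color is available to be transparent.
#' Dot exemplars are stored with positional encoding noise
#' `sigma_encode_dot`: arbitrary positions are costly to memorize precisely,
#' which is what makes the receiver the bottleneck when iconicity is absent
#' on their side. With probability `epsilon_guess` the receiver lapses and
#' guesses uniformly.
#'
#' @param memory_capacity Maximum exemplars retained per referent.
#' @param lambda_prior Weight in `[0, 1]` of the iconic prior for color views.
#' @param epsilon_guess Lapse probability.
#' @param tau_color Kernel bandwidth for color similarity, Lab units.
#' @param tau_dot Kernel bandwidth for dot similarity, pad units.
#' @param sigma_encode_dot SD of encoding noise added when storing dot
#'   exemplars, pad units.
#' @param prior_anchors Anchor matrix defining the receiver's color
#'   associations (defaults to [default_anchors()]).
#' @return A `receiver_params` list.
#' @export
receiver_params <- function(memory_capacity = 6, lambda_prior = 0.6,
                            epsilon_guess = 0.1, tau_color = 40,
                            tau_dot = 0.12, sigma_encode_dot = 0.28,
                            prior_anchors = default_anchors()) {
  stopifnot(memory_capacity >= 1, lambda_prior >= 0, lambda_prior <= 1,
            epsilon_guess >= 0, epsilon_guess <= 1,
            tau_color > 0, tau_dot > 0, sigma_encode_dot >= 0)
  structure(list(memory_capacity = memory_capacity,
                 lambda_prior = lambda_prior,
                 epsilon_guess = epsilon_guess,
                 tau_color = tau_color, tau_dot = tau_dot,
                 sigma_encode_dot = sigma_encode_dot,
                 prior_anchors = prior_anchors),
            class = "receiver_params")
}

#' Create receiver agent state
#'
#' @param params A [receiver_params()] object.
#' @return Receiver state with empty exemplar memory. `pinned` holds
#'   exemplars from a persistent log panel (see
#'   [run_receiver_only_session()]) that are never evicted.
#' @export
receiver_new <- function(params = receiver_params()) {
  empty <- stats::setNames(vector("list", length(referents())), referents())
  structure(list(params = params, exemplars = empty, pinned = empty,
                 anchor_lab = pad_to_lab(params$prior_anchors[, "u"],
                                         params$prior_anchors[, "v"])),
            class = "receiver_state")
}

view_features <- function(view) {
  switch(view$kind,
    color = unname(view$payload[c("L", "a", "b")]),
    dot = unname(view$payload[c("u", "v")]),
    stop("cannot extract features from a blank view")
  )
}

best_similarity <- function(feats, mat, tau) {
  if (is.null(mat) || nrow(mat) == 0) return(0)
  d2 <- colSums((t(mat) - feats)^2)
  exp(-min(d2) / tau^2)
}

#' Guess the referent for a viewed signal
#'
#' Scores every referent by
#' `(1 - lambda) * exemplar similarity + lambda * iconic prior` (with
#' `lambda = 0` for dot views), lapses uniformly with probability
#' `epsilon_guess`, and returns the argmax with uniform tie-breaking.
#'
#' @param state A [receiver_new()] state.
#' @param view A non-blank [render_view()] result.
#' @return List with `guess` (referent label) and `scores` (named numeric).
#' @export
receiver_guess <- function(state, view) {
  if (view$kind == "blank") stop("cannot guess from a blank view")
  p <- state$params
  refs <- referents()
  if (stats::runif(1) < p$epsilon_guess) {
    return(list(guess = sample(refs, 1), scores = NULL))
  }
  feats <- view_features(view)
  is_color <- view$kind == "color"
  lambda <- if (is_color) p$lambda_prior else 0
  tau <- if (is_color) p$tau_color else p$tau_dot
  scores <- vapply(refs, function(r) {
    sim <- max(best_similarity(feats, state$exemplars[[r]], tau),
               best_similarity(feats, state$pinned[[r]], tau))
    pri <- if (is_color) {
      exp(-sum((feats - state$anchor_lab[r, ])^2) / p$tau_color^2)
    } else 0
    (1 - lambda) * sim + lambda * pri
  }, numeric(1))
  top <- which(scores == max(scores))
  pick <- if (length(top) > 1) sample(top, 1) else top
  list(guess = refs[pick], scores = scores)
}

#' Store a feedback exemplar
#'
#' Called after feedback each round: appends the `(view, true referent)`
#' pair to exemplar memory, evicting the oldest exemplar beyond
#' `memory_capacity`. Dot views are stored with Gaussian encoding noise
#' (see [receiver_params()]); pinned log exemplars bypass both noise and
#' eviction via `pin = TRUE`.
#'
#' @param state A [receiver_new()] state.
#' @param view The view the receiver saw.
#' @param true_referent The round's target, revealed at feedback.
#' @param pin Store as a permanent pinned exemplar (log panel).
#' @return Updated receiver state.
#' @export
receiver_learn <- function(state, view, true_referent, pin = FALSE) {
  if (view$kind == "blank") return(state)
  if (!true_referent %in% referents()) {
    stop("unknown referent: ", true_referent)
  }
  feats <- view_features(view)
  if (pin) {
    state$pinned[[true_referent]] <-
      rbind(state$pinned[[true_referent]], feats)
    return(state)
  }
  if (view$kind == "dot" && state$params$sigma_encode_dot > 0) {
    feats <- clamp01(feats + stats::rnorm(2, 0, state$params$sigma_encode_dot))
  }
  mem <- rbind(state$exemplars[[true_referent]], feats)
  if (nrow(mem) > state$params$memory_capacity) {
    mem <- mem[(nrow(mem) - state$params$memory_capacity + 1):nrow(mem), ,
               drop = FALSE]
  }
  state$exemplars[[true_referent]] <- mem
  state
}
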