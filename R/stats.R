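coef_table <- function(cf, df = NULL) {
  tb <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, 1]),
    std_error = unname(cf[, 2])
  )
  if (!is.null(df)) tb$df <- unname(df)
  tb$statistic <- unname(cf[, grep("value$", colnames(cf))[1]])
  tb$p_value <- unname(cf[, ncol(cf)])
  tb
}

relevel_condition <- function(x, reference) {
  x <- factor(x)
  if (!reference %in% levels(x)) {
    stop("reference level '", reference, "' not present in the data")
  }
  stats::relevel(x, ref = reference)
}

#' Dyad-level condition contrast (ordinary least squares)
#'
#' Fits `dv ~ condition` over the per-dyad table with treatment coding and
#' a configurable reference level (low iconicity by default, so the
#' coefficients are the high-vs-low and one-sided-vs-low contrasts).
#'
#' @param per_dyad A [per_dyad_summary()] tibble (or any data frame with a
#'   `condition` column and the chosen `dv`).
#' @param dv Name of the dependent variable column.
#' @param reference Reference condition level.
#' @return A tibble coefficient table (`term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`) with attributes `r_squared` and `model` (the
#'   underlying `lm` fit).
#' @export
fit_condition_lm <- function(per_dyad, dv = "success_index",
                             reference = "low") {
  stopifnot(dv %in% names(per_dyad), "condition" %in% names(per_dyad))
  d <- as.data.frame(per_dyad)
  d$condition <- relevel_condition(d$condition, reference)
  if (nlevels(d$condition) < 2) {
    stop("need at least two conditions to contrast")
  }
  fit <- stats::lm(stats::reformulate("condition", response = dv), data = d)
  sm <- summary(fit)
  tb <- coef_table(sm$coefficients)
  attr(tb, "r_squared") <- sm$r.squared
  attr(tb, "model") <- fit
  tb
}

#' Two-factor contrast for receiver-only sessions
#'
#' Crossed two-by-two summary for the receiver-only paradigm: signal type
#' (color vs dot) by presence of the signal log, with their interaction,
#' on a per-participant dependent variable.
#'
#' @param per_participant Data frame with columns `signal_type`
#'   (`"color"`/`"dot"`), `log_panel` (logical), and the chosen `dv`.
#' @param dv Dependent-variable column name.
#' @return Coefficient table as in [fit_condition_lm()]; reference cell is
#'   dot without log.
#' @export
fit_followup_lm <- function(per_participant, dv = "success_index") {
  stopifnot(all(c("signal_type", "log_panel", dv) %in%
                  names(per_participant)))
  d <- as.data.frame(per_participant)
  d$signal_type <- stats::relevel(factor(d$signal_type), ref = "dot")
  d$log_panel <- factor(d$log_panel, levels = c(FALSE, TRUE))
  fit <- stats::lm(
    stats::reformulate("signal_type * log_panel", response = dv), data = d)
  sm <- summary(fit)
  tb <- coef_table(sm$coefficients)
  attr(tb, "r_squared") <- sm$r.squared
  attr(tb, "model") <- fit
  tb
}

r2_lmm <- function(fit) {
  # Nakagawa-style decomposition for a Gaussian LMM with intercept-only
  # random effects: marginal = fixed variance over total, conditional adds
  # the random-intercept variances.
  var_fix <- stats::var(as.numeric(stats::model.matrix(fit) %*%
                                     lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_ran <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  var_res <- attr(vc, "sc")^2
  tot <- var_fix + var_ran + var_res
  c(marginal = var_fix / tot, conditional = (var_fix + var_ran) / tot)
}

#' Signal-stability mixed model
#'
#' REML linear mixed-effects model of stability distance on condition, with
#' crossed random intercepts for dyad and referent and Satterthwaite degrees
#' of freedom for the t tests. The reference level is configurable so the
#' high-vs-one-sided contrast can be read off a refit.
#'
#' @param stability A [stability_observations()] tibble.
#' @param reference Reference condition level.
#' @return Coefficient table with `df`; attributes `r_squared` (marginal and
#'   conditional), `model`, and `converged`.
#' @export
fit_stability_lmm <- function(stability, reference = "low") {
  d <- as.data.frame(stability)
  stopifnot(all(c("distance", "condition", "dyad_id", "referent") %in%
                  names(d)))
  d$condition <- relevel_condition(d$condition, reference)
  fit <- lmerTest::lmer(
    distance ~ condition + (1 | dyad_id) + (1 | referent),
    data = d, REML = TRUE)
  sm <- summary(fit)
  cf <- sm$coefficients
  tb <- coef_table(cf[, -3, drop = FALSE], df = cf[, "df"])
  attr(tb, "r_squared") <- r2_lmm(fit)
  attr(tb, "model") <- fit
  msgs <- fit@optinfo$conv$lme4$messages
  attr(tb, "converged") <- is.null(msgs)
  if (!is.null(msgs)) {
    warning("stability model convergence messages: ",
            paste(msgs, collapse = "; "))
  }
  tb
}

#' Round-by-round mixed models
#'
#' The two-part analysis of the established-count series. Part one is a
#' binomial GLMM for whether any signal is established in a round
#' (`presence ~ round_z * condition + (1 | dyad_id)`); part two is a
#' negative-binomial GLMM for the established count restricted to rounds
#' with at least one signal, with the same fixed and random structure. The
#' split handles the mass of zero-signal rounds separately from growth in
#' the established set.
#'
#' @param rounds A [round_table()] tibble.
#' @param reference Reference condition level.
#' @return List with coefficient tables `presence` and `count`, each
#'   carrying `model` and `converged` attributes.
#' @export
fit_round_glmms <- function(rounds, reference = "low") {
  d <- as.data.frame(rounds)
  stopifnot(all(c("presence", "s", "round_z", "condition", "dyad_id") %in%
                  names(d)))
  d$condition <- relevel_condition(d$condition, reference)
  if (length(unique(d$presence)) < 2) {
    stop("degenerate response: presence indicator is constant")
  }
  pres <- lme4::glmer(presence ~ round_z * condition + (1 | dyad_id),
                      data = d, family = stats::binomial())
  sm_p <- summary(pres)
  tb_p <- coef_table(sm_p$coefficients)
  attr(tb_p, "model") <- pres
  attr(tb_p, "converged") <- is.null(pres@optinfo$conv$lme4$messages)

  dn <- d[d$s > 0, , drop = FALSE]
  if (nrow(dn) == 0) stop("degenerate response: no rounds with s > 0")
  cnt <- glmmTMB::glmmTMB(s ~ round_z * condition + (1 | dyad_id),
                          data = dn, family = glmmTMB::nbinom2())
  sm_c <- summary(cnt)
  tb_c <- coef_table(sm_c$coefficients$cond)
  attr(tb_c, "model") <- cnt
  attr(tb_c, "converged") <- isTRUE(cnt$fit$convergence == 0)
  list(presence = tb_p, count = tb_c)
}
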