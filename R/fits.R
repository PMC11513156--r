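# Convenience wrappers around fit_mcmc() for the five model families.

#' Fit the reproductive-state transition model
#'
#' Multinomial-logit model of the destination state (subordinate reference,
#' sneaker, guard) at the next oestrus event, conditional on surviving to
#' it, with crossed event/group/male random effects. Run once with the
#' `age_rank` variant and once with `quadratic_age` to separate rank and
#' senescence effects, as the two covariates are collinear.
#'
#' @param transitions transition table from [preprocess_cohort()] /
#'   [build_transition_table()]; `"dead"` outcomes are dropped internally.
#' @param variant `"age_rank"` or `"quadratic_age"`.
#' @param ... passed to [model_spec()].
#' @param scaler optional fixed [covariate_scaler].
#' @return A `posterior_draws` object.
#' @export
fit_transition <- function(transitions, variant = "age_rank", ..., scaler = NULL) {
  fit_mcmc(model_spec("transition", variant = variant, ...), transitions, scaler)
}

#' Fit the mortality model
#'
#' Bernoulli model of dying before the next oestrus event, with
#' state-specific intercepts, state-specific group-centred-weight slopes,
#' the variant's age term(s) and the standardized time to the next event.
#'
#' @inheritParams fit_transition
#' @export
fit_mortality <- function(transitions, variant = "age_rank", ..., scaler = NULL) {
  fit_mcmc(model_spec("mortality", variant = variant, ...), transitions, scaler)
}

#' Fit the binomial paternity-share model
#'
#' Number of pups sired by each male in an oestrus event, binomial with the
#' event's total assigned pups as trials, logit-linear in group-centred
#' weight plus the variant's age term(s).
#'
#' @param paternity paternity design table from [preprocess_cohort()].
#' @inheritParams fit_transition
#' @export
fit_paternity <- function(paternity, variant = "age_rank", ..., scaler = NULL) {
  fit_mcmc(model_spec("paternity", variant = variant, ...), paternity, scaler)
}

#' Fit the Gaussian oestrus weight-change model
#'
#' Percentage weight change over an oestrus event regressed on behavioural
#' state (subordinate versus guard). Age is deliberately not a covariate
#' (collinear with state). Besides the raw coefficients, the returned fit
#' carries two derived parameters: `mean_subordinate` (the intercept) and
#' `mean_guard` (intercept + guard contrast), each with full posterior
#' draws, and a `$state_contrast` summary reporting whether the guard mean
#' credible interval excludes 0 while the subordinate one spans it.
#'
#' @param weight_change design table with `state` and `pct_change`.
#' @param ... passed to [model_spec()].
#' @export
fit_weight_change <- function(weight_change, ...) {
  fit <- fit_mcmc(model_spec("weight_change", prior = list(beta_sd = 5), ...),
                  weight_change, NULL)
  d <- fit$draws
  extra <- array(NA_real_, c(dim(d)[1], dim(d)[2], 2),
                 dimnames = list(NULL, NULL, c("mean_subordinate", "mean_guard")))
  extra[, , "mean_subordinate"] <- d[, , "(Intercept)"]
  extra[, , "mean_guard"] <- d[, , "(Intercept)"] + d[, , "state_guard"]
  dn <- c(dimnames(d)[[3]], dimnames(extra)[[3]])
  all <- array(c(d, extra), c(dim(d)[1], dim(d)[2], dim(d)[3] + 2),
               dimnames = list(NULL, NULL, dn))
  fit$draws <- all
  fit$rhat <- rhat(fit)
  fit$summary <- summarize_draws(all, fit$rhat)
  ci <- function(p) quantile(c(all[, , p]), c(0.025, 0.975))
  g <- ci("mean_guard"); s <- ci("mean_subordinate")
  fit$state_contrast <- list(
    guard_ci = g, subordinate_ci = s,
    guard_excludes_zero = g[1] > 0 || g[2] < 0,
    subordinate_spans_zero = s[1] <= 0 && s[2] >= 0)
  fit
}

#' Fit the zero-inflated negative binomial LRS model
#'
#' Lifetime reproductive success (pedigree-assigned offspring over a male's
#' life) regressed on condition at first guarding activity: group-centred
#' weight and age rank (`"relative"` variant) or absolute weight and age
#' (`"absolute"`), with a group random intercept in the count component and
#' an intercept-only zero-inflation part.
#'
#' @param lrs design table from [preprocess_cohort()] or [simulate_lrs()].
#' @param variant `"relative"` or `"absolute"`.
#' @inheritParams fit_transition
#' @export
fit_lrs <- function(lrs, variant = "relative", ..., scaler = NULL) {
  fit_mcmc(model_spec("lrs", variant = variant, ...), lrs, scaler)
}
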