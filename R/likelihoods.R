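# Exact log-likelihoods on the R side. These are the reference
# implementations of the model densities (full normalizing constants); the
# compiled sampler uses the same kernels with constants dropped.

# sum random-effect contributions for rows of `data`; re is a list with
# optional elements event/group/male, each a named vector (or named matrix
# with one column per multinomial destination)
re_eta <- function(data, re, ncol_eta = 1) {
  eta <- matrix(0, nrow(data), ncol_eta)
  if (is.null(re)) return(eta)
  keys <- c(event = "event_from", group = "group_id", male = "male_id")
  for (f in names(re)) {
    key <- if (f %in% names(keys)) keys[[f]] else f
    col <- data[[key]]
    if (is.null(col) && f == "event") col <- data[["event_id"]]
    v <- re[[f]]
    if (is.matrix(v)) eta <- eta + v[col, , drop = FALSE]
    else eta <- eta + matrix(v[col], nrow(data), ncol_eta)
  }
  eta
}

#' Multistate transition log-likelihood (conditional on survival)
#'
#' Sum over survivor intervals of the multinomial-logit log probability of
#' the observed destination state, with subordinate as the reference
#' destination. Destination probabilities per row sum to one by
#' construction.
#'
#' @param beta coefficient matrix: rows are design columns (see
#'   [design_transition()]), columns `sneaker` and `guard`.
#' @param data transition observations restricted to survivors (no `"dead"`
#'   outcomes), original covariate scales.
#' @param scaler persisted [covariate_scaler] used at fit time.
#' @param variant `"age_rank"` or `"quadratic_age"`.
#' @param share_slopes covariate slopes shared across origin states.
#' @param re optional realized random effects: list with elements among
#'   `event`, `group`, `male`, each a named matrix (levels x 2 destinations).
#' @return Scalar log-likelihood.
#' @export
transition_loglik <- function(beta, data, scaler, variant = "quadratic_age",
                              share_slopes = TRUE, re = NULL) {
  if (any(data$outcome == "dead"))
    stop("transition_loglik is conditional on survival; 'dead' outcomes belong to mortality_loglik")
  X <- design_transition(data, variant, scaler, share_slopes)
  eta <- X[, rownames(beta), drop = FALSE] %*% beta + re_eta(data, re, ncol(beta))
  denom <- log1p(exp(eta[, 1]) + exp(eta[, 2]))
  lin <- ifelse(data$outcome == "sneaker", eta[, 1],
                ifelse(data$outcome == "guard", eta[, 2], 0))
  sum(lin - denom)
}

#' Mortality log-likelihood
#'
#' Bernoulli log-likelihood of dying before the next oestrus event, with
#' logit(p) built from state-specific intercepts, state-specific
#' group-centred-weight slopes, the variant's age term(s) and the
#' standardized time to the next event.
#'
#' @param beta named coefficient vector matching [design_mortality()]
#'   columns.
#' @param data all transition observations (any outcome), original scales.
#' @inheritParams transition_loglik
#' @param re optional list of named vectors (levels) per factor.
#' @export
mortality_loglik <- function(beta, data, scaler, variant = "quadratic_age", re = NULL) {
  if (any(data$interval_days < 0)) stop("interval_days must be >= 0")
  X <- design_mortality(data, variant, scaler)
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta) + drop(re_eta(data, re, 1))
  y <- as.numeric(data$outcome == "dead")
  sum(y * eta - log1p(exp(eta)))
}

#' Binomial paternity-share log-likelihood
#'
#' Each male's pups sired in an event are binomial with the event's total
#' assigned pups as the number of trials and logit(p) linear in group-centred
#' weight (plus the variant's age terms and random effects). Includes the
#' binomial coefficient, so values are exact log pmfs.
#'
#' @param beta named coefficient vector (`(Intercept)`, `gcw`, age terms).
#' @param data paternity observations with `sired`, `event_total` and
#'   covariates.
#' @inheritParams mortality_loglik
#' @export
paternity_loglik <- function(beta, data, scaler, variant = "age_rank", re = NULL) {
  if (any(data$sired > data$event_total)) stop("sired exceeds event_total")
  X <- design_paternity(data, variant, scaler)
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta) + drop(re_eta(data, re, 1))
  sum(dbinom(data$sired, data$event_total, plogis(eta), log = TRUE))
}

#' Gaussian weight-change log-likelihood
#'
#' @param beta named vector (`(Intercept)`, `state_guard`): subordinate mean
#'   and guard contrast, in percent of pre-oestrus body weight.
#' @param sigma residual SD (> 0).
#' @param data weight-change observations with `state` and `pct_change`.
#' @param re optional list of named vectors per factor.
#' @export
gaussian_loglik <- function(beta, sigma, data, re = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  X <- design_weight_change(data)
  mu <- drop(X[, names(beta), drop = FALSE] %*% beta) + drop(re_eta(data, re, 1))
  sum(dnorm(data$pct_change, mu, sigma, log = TRUE))
}

#' Zero-inflated negative binomial log pmf
#'
#' Mixture of a point mass at zero (probability `pi`) and a negative binomial
#' with mean `mu` and dispersion `phi` (variance `mu + mu^2 / phi`):
#' `P(0) = pi + (1 - pi) NB(0; mu, phi)`, `P(k > 0) = (1 - pi) NB(k; mu,
#' phi)`.
#'
#' @param k non-negative counts (vectorized).
#' @param pi zero-inflation probability in `[0, 1]`.
#' @param mu negative binomial mean (> 0).
#' @param phi dispersion (> 0); larger is closer to Poisson.
#' @return Log probabilities.
#' @examples
#' exp(zinb_logpmf(0, pi = 1, mu = 3, phi = 1))  # 1: degenerate mixture
#' @export
zinb_logpmf <- function(k, pi, mu, phi) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be non-negative integers")
  if (any(pi < 0 | pi > 1)) stop("pi must be in [0, 1]")
  if (any(mu <= 0) || any(phi <= 0)) stop("mu and phi must be > 0")
  lnb <- dnbinom(k, size = phi, mu = mu, log = TRUE)
  ifelse(k == 0,
         log(pi + (1 - pi) * exp(lnb)),
         log1p(-pi) + lnb)
}
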