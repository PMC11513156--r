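#' Four-state transition matrix at a covariate vector
#'
#' Composes the mortality and transition submodels into the full
#' discrete-time transition matrix over states (subordinate, sneaker, guard,
#' dead) for one covariate vector: each live row is
#' `(1 - p_death) * softmax(live destinations)` with `p_death` from the
#' mortality model, and the dead row is absorbing. Random effects are set to
#' zero (population level); covariates are given on the original scale and
#' standardized internally with the supplied scaler.
#'
#' @param transition_beta coefficient matrix (design columns x destinations
#'   `sneaker`, `guard`), as in [true_params()]`$transition$beta`.
#' @param mortality_beta named coefficient vector matching
#'   [design_mortality()] columns.
#' @param covariates named list or one-row data.frame with `age`,
#'   `age_rank`, `gcw`, `interval_days` on their original scales.
#' @param scaler [covariate_scaler] persisted from fitting (or
#'   [scaler_from_params()]).
#' @param variant `"age_rank"` or `"quadratic_age"`.
#' @param share_slopes slope-sharing of the transition design.
#' @return 4 x 4 matrix, rows = origin (subordinate, sneaker, guard, dead),
#'   columns = destination; every row sums to 1.
#' @export
transition_matrix_at <- function(transition_beta, mortality_beta, covariates,
                                 scaler, variant = "quadratic_age",
                                 share_slopes = TRUE) {
  if (is.null(scaler)) stop("a covariate scaler is required")
  d <- as.data.frame(covariates)[rep(1, 3), , drop = FALSE]
  d$origin_state <- LIVE_STATES
  Xt <- design_transition(d, variant, scaler, share_slopes)
  Xm <- design_mortality(d, variant, scaler)
  eta <- Xt[, rownames(transition_beta), drop = FALSE] %*% transition_beta
  pd <- plogis(drop(Xm[, names(mortality_beta), drop = FALSE] %*% mortality_beta))
  eK <- exp(eta[, "sneaker"]); eG <- exp(eta[, "guard"])
  denom <- 1 + eK + eG
  live <- cbind(1 / denom, eK / denom, eG / denom) * (1 - pd)
  m <- rbind(cbind(live, pd), c(0, 0, 0, 1))
  dimnames(m) <- list(STATES, STATES)
  m
}

#' Posterior-predictive probability curve over a covariate grid
#'
#' For every retained draw, computes the requested probability at each grid
#' point with random effects at zero and non-focal covariates held at their
#' training-sample means, then summarizes the pointwise posterior mean and
#' equal-tailed 95% credible interval. Model-specific responses:
#' transition fits give the probability of moving from `origin` to
#' `destination` conditional on survival; mortality fits give the
#' probability of dying before the next event from `origin`; paternity fits
#' give the per-pup siring probability (or expected pups per event with
#' `response = "count"`); LRS fits give the expected lifetime reproductive
#' success `(1 - pi) * mu`.
#'
#' @param fit a `posterior_draws` object.
#' @param covariate focal covariate name (original scale).
#' @param grid numeric grid for the focal covariate; values outside the
#'   observed support trigger an extrapolation warning.
#' @param origin,destination origin/destination states for multistate fits.
#' @param reference named overrides for non-focal covariates.
#' @param response paternity fits: `"probability"` or `"count"`.
#' @return data.frame of class `prediction_curve` with the grid, posterior
#'   `mean`, `lower` and `upper`.
#' @export
predict_curve <- function(fit, covariate, grid, origin = "subordinate",
                          destination = "guard", reference = NULL,
                          response = c("probability", "count")) {
  response <- match.arg(response)
  spec <- fit$spec
  if (spec$model == "weight_change")
    stop("weight-change fits have two state means, not a covariate curve; see fit_weight_change()")
  covs <- spec_covariates(spec)
  if (!covariate %in% covs)
    stop("unknown covariate '", covariate, "'; model uses: ", paste(covs, collapse = ", "))
  rel <- involved_params(fit, origin, destination)
  bad_r <- fit$rhat[rel][fit$rhat[rel] >= 1.1]
  if (length(bad_r))
    warning("R-hat >= 1.1 for involved parameters: ",
            paste(names(bad_r), collapse = ", "), call. = FALSE)
  sup <- fit$support[[covariate]]
  if (!is.null(sup) && (min(grid) < sup[1] || max(grid) > sup[2]))
    warning("grid extends beyond the observed support of '", covariate,
            "' [", round(sup[1], 2), ", ", round(sup[2], 2), "]; extrapolating",
            call. = FALSE)

  nd <- as.data.frame(as.list(fit$data_means))[rep(1, length(grid)), , drop = FALSE]
  for (nm in names(reference)) nd[[nm]] <- reference[[nm]]
  nd[[covariate]] <- grid
  if (spec$model %in% c("transition", "mortality")) nd$origin_state <- origin

  X <- switch(spec$model,
    transition = design_transition(nd, spec$variant, fit$scaler, spec$share_slopes),
    mortality = design_mortality(nd, spec$variant, fit$scaler, spec$time_interactions),
    paternity = design_paternity(nd, spec$variant, fit$scaler),
    lrs = design_lrs(nd, spec$variant, fit$scaler))

  dm <- draws_matrix(fit)
  n_draws <- nrow(dm)
  vals <- matrix(NA_real_, n_draws, length(grid))
  if (spec$model == "transition") {
    kdest <- match(destination, LIVE_STATES)
    if (is.na(kdest)) stop("destination must be a live state")
    ks <- paste0("sneaker:", colnames(X)); gs <- paste0("guard:", colnames(X))
    for (i in seq_len(n_draws)) {
      eK <- drop(X %*% dm[i, ks]); eG <- drop(X %*% dm[i, gs])
      denom <- 1 + exp(eK) + exp(eG)
      vals[i, ] <- switch(kdest, 1 / denom, exp(eK) / denom, exp(eG) / denom)
    }
  } else if (spec$model == "mortality") {
    for (i in seq_len(n_draws)) vals[i, ] <- plogis(drop(X %*% dm[i, colnames(X)]))
  } else if (spec$model == "paternity") {
    for (i in seq_len(n_draws)) vals[i, ] <- plogis(drop(X %*% dm[i, colnames(X)]))
    if (response == "count") vals <- vals * fit$mean_event_total
  } else { # lrs
    for (i in seq_len(n_draws)) {
      mu <- exp(drop(X %*% dm[i, colnames(X)]))
      pi0 <- plogis(dm[i, "zero:(Intercept)"])
      vals[i, ] <- (1 - pi0) * mu
    }
  }
  out <- data.frame(covariate = covariate, value = grid,
                    mean = colMeans(vals),
                    lower = apply(vals, 2, quantile, 0.025),
                    upper = apply(vals, 2, quantile, 0.975))
  class(out) <- c("prediction_curve", "data.frame")
  out
}

# fixed effects enter every prediction; RE SDs do not (REs are set to zero)
involved_params <- function(fit, origin, destination) {
  nm <- names(fit$rhat)
  nm[!grepl("^sd_", nm)]
}

#' Raw mortality contingency summary
#'
#' Classifies every interval by origin state (guards versus subordinates;
#' sneaker intervals are excluded and counted separately) and by weight
#' class (group-centred weight strictly below 0 versus average-and-above),
#' then tabulates deaths before the next oestrus event. Percentages are
#' `100 * deaths / totals` rounded to one decimal; empty cells report `NA`,
#' not 0.
#'
#' @param transitions transition table with `origin_state`, `outcome`,
#'   `gcw`.
#' @return data.frame with one row per state x weight-class cell
#'   (`deaths`, `totals`, `percent`); attribute `n_sneaker_excluded`.
#' @export
summarize_raw_mortality <- function(transitions) {
  if (any(is.na(transitions$gcw))) stop("group-centred weight required on every row")
  keep <- transitions$origin_state %in% c("guard", "subordinate")
  t2 <- transitions[keep, ]
  cells <- expand.grid(state = c("guard", "subordinate"),
                       weight_class = c("below_average", "average_and_above"),
                       stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- t2$origin_state == cells$state[i] &
      (if (cells$weight_class[i] == "below_average") t2$gcw < 0 else t2$gcw >= 0)
    tot <- sum(sel); dth <- sum(sel & t2$outcome == "dead")
    data.frame(state = cells$state[i], weight_class = cells$weight_class[i],
               deaths = dth, totals = tot,
               percent = if (tot > 0) round(100 * dth / tot, 1) else NA_real_)
  }))
  attr(res, "n_sneaker_excluded") <- sum(!keep)
  res
}

#' Posterior switch point of the quadratic age effect
#'
#' For quadratic-age fits, the age at which the guarding linear predictor
#' peaks: `-b1 / (2 b2)` on the standardized scale, back-transformed through
#' the persisted scaler. Draws with `b2 = 0` are skipped and counted; if the
#' posterior mass of `b2` is not predominantly negative there is no interior
#' maximum and the upper support boundary is reported with a warning.
#'
#' @param fit a quadratic-age `posterior_draws` (transition model).
#' @param destination destination whose curve is analysed (default guard).
#' @param origin origin state used when slopes are origin-specific.
#' @return List with `mean`, `q2.5`, `q97.5`, `n_skipped`, `boundary`.
#' @export
quadratic_switch_point <- function(fit, destination = "guard",
                                   origin = "subordinate") {
  if (fit$spec$variant != "quadratic_age")
    stop("switch point requires a quadratic_age fit")
  dm <- draws_matrix(fit)
  suf <- if (fit$spec$model == "transition" && !fit$spec$share_slopes)
    paste0(":", ORIGIN_COLS[[origin]]) else ""
  pre <- if (fit$spec$model == "transition") paste0(destination, ":") else ""
  b1 <- dm[, paste0(pre, "age", suf)]
  b2 <- dm[, paste0(pre, "age2", suf)]
  skip <- b2 == 0
  n_skip <- sum(skip)
  if (mean(b2[!skip] < 0) < 0.5) {
    warning("posterior mass of the quadratic term is not predominantly negative; ",
            "no interior maximum, reporting the support boundary", call. = FALSE)
    bound <- if (!is.null(fit$support$age)) fit$support$age[2] else NA_real_
    return(list(mean = bound, q2.5 = NA_real_, q97.5 = NA_real_,
                n_skipped = n_skip, boundary = TRUE))
  }
  z <- -b1[!skip] / (2 * b2[!skip])
  age <- scaler_invert(fit$scaler, z, "age")
  list(mean = mean(age), q2.5 = unname(quantile(age, 0.025)),
       q97.5 = unname(quantile(age, 0.975)), n_skipped = n_skip,
       boundary = FALSE)
}
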