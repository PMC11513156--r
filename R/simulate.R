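#' Interval outcome probabilities under the generative law
#'
#' For each row (one male observed at one oestrus event, with covariates and
#' the time to the next event), composes the Bernoulli mortality submodel and
#' the conditional multinomial-logit transition submodel into the four
#' outcome probabilities for the next event: remain/become subordinate,
#' sneaker, guard, or die beforehand. Random effects default to zero
#' (population level) but realized values can be supplied.
#'
#' @param params a [true_params()] object.
#' @param data data.frame with columns `origin_state`, `age`, `age_rank`,
#'   `gcw`, `interval_days` (original scales; standardized internally with
#'   the generator's fixed scaler).
#' @param trans_re matrix (rows of `data` x 2, destinations sneaker/guard) of
#'   summed transition random effects, or 0.
#' @param mort_re vector of summed mortality random effects, or 0.
#' @return Matrix `nrow(data)` x 4 with columns `subordinate`, `sneaker`,
#'   `guard`, `dead`; rows sum to 1.
#' @export
outcome_probs <- function(params, data, trans_re = 0, mort_re = 0) {
  scaler <- scaler_from_params(params)
  Xt <- design_transition(data, params$variant, scaler, share_slopes = TRUE)
  Xm <- design_mortality(data, params$variant, scaler)
  eta <- Xt %*% params$transition$beta + trans_re
  em <- drop(Xm %*% params$mortality$beta) + mort_re
  pd <- plogis(em)
  eK <- exp(eta[, "sneaker"]); eG <- exp(eta[, "guard"])
  denom <- 1 + eK + eG
  cbind(subordinate = (1 - pd) / denom,
        sneaker     = (1 - pd) * eK / denom,
        guard       = (1 - pd) * eG / denom,
        dead        = pd)
}

#' Simulate interval outcomes for given covariate rows
#'
#' Draws one outcome (destination state or death) per row from
#' [outcome_probs()] at the population level. Useful for Monte-Carlo checks
#' of the generative law on fixed covariate grids.
#'
#' @inheritParams outcome_probs
#' @param seed optional integer seed.
#' @return Character vector of outcomes (`"subordinate"`, `"sneaker"`,
#'   `"guard"`, `"dead"`).
#' @export
simulate_transitions <- function(params, data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- outcome_probs(params, data)
  u <- runif(nrow(p))
  cum <- t(apply(p, 1, cumsum))
  STATES[1L + rowSums(u > cum)]
}

#' Simulate a complete synthetic cohort
#'
#' Generates a full dataset bundle mirroring the field data structure: male
#' life histories (birth/death), per-group oestrus event schedules, per-event
#' reproductive states drawn from the same mortality + multinomial-logit
#' structure the inference modules fit (with crossed event/group/male random
#' effects), pre- and post-oestrus body weights from a saturating growth
#' curve with individual frailty and state-dependent oestrus weight change,
#' and weight-skewed paternity allocations for a subset of events.
#'
#' All males enter each oestrus event of their group from sexual maturity
#' (`adult_age`) until death; death is absorbing; a male's first observed
#' state is subordinate. Death dates of males dying between events fall
#' inside the interval; males alive after their group's last event receive a
#' post-observation death date (exponential, mean 240 days), so the
#' longer-than-a-year-to-death inclusion filter is exercised downstream.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `cohort_bundle` with data.frames `males`,
#'   `events`, `states`, `paternity`, `weights`, plus `true_params` and
#'   `config`. Days are numeric offsets from an arbitrary origin;
#'   [write_bundle()] exports ISO 8601 dates.
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  set.seed(config$seed)
  tp <- config$true_params
  g_par <- tp$growth
  horizon <- config$years * 365.25
  adult_days <- config$adult_age * 365.25

  males_l <- list(); events_l <- list(); states_l <- list()
  pat_l <- list(); weights_l <- list()

  for (g in seq_len(config$n_groups)) {
    gid <- sprintf("G%02d", g)
    ev <- schedule_events(config$years, config$events_per_year, config$event_jitter)
    if (nrow(ev) == 0) next
    ev$event_id <- sprintf("%s-E%03d", gid, seq_len(nrow(ev)))
    nE <- nrow(ev)

    # males: initial stock plus Poisson recruitment over the window
    n0 <- max(1L, round(config$mean_adult_males_per_group))
    age0 <- config$adult_age + pmin(rexp(n0, 0.35), 9.5)
    n_rec <- rpois(1, 0.3 * config$mean_adult_males_per_group * config$years)
    birth <- c(-age0 * 365.25, runif(n_rec, -adult_days, horizon))
    nM <- length(birth)
    mid <- sprintf("%s-M%03d", gid, seq_len(nM))
    frailty <- rnorm(nM, 0, g_par$frailty_sd)

    # realized random effects (latent truth, not exported)
    u_ev_t <- matrix(rnorm(nE * 2, 0, tp$transition$sd["event"]), nE, 2)
    u_ev_m <- rnorm(nE, 0, tp$mortality$sd["event"])
    u_gr_t <- rnorm(2, 0, tp$transition$sd["group"])
    u_gr_m <- rnorm(1, 0, tp$mortality$sd["group"])
    u_ma_t <- matrix(rnorm(nM * 2, 0, tp$transition$sd["male"]), nM, 2)
    u_ma_m <- rnorm(nM, 0, tp$mortality$sd["male"])
    wc <- tp$weight_change
    u_ev_w <- rnorm(nE, 0, wc$re_sd["event"])
    u_gr_w <- rnorm(1, 0, wc$re_sd["group"])
    u_ma_w <- rnorm(nM, 0, wc$re_sd["male"])
    u_ma_p <- rnorm(nM, 0, tp$paternity$sd_male)

    state <- rep(NA_character_, nM)   # current state; NA until first event
    death <- rep(NA_real_, nM)
    last_event_end <- rep(NA_real_, nM)

    for (i in seq_len(nE)) {
      s0 <- ev$start_day[i]; e0 <- ev$end_day[i]
      present <- which(birth + adult_days <= s0 & is.na(death))
      if (!length(present)) next
      state[present][is.na(state[present])] <- "subordinate"
      age <- (s0 - birth[present]) / 365.25
      w_pre <- pmax(growth_curve(age, g_par, frailty[present]) +
                      rnorm(length(present), 0, g_par$measurement_sd), 300)
      gcw <- w_pre - mean(w_pre)
      rk <- integer(length(present))
      rk[order(-age, mid[present])] <- seq_along(present)

      states_l[[length(states_l) + 1L]] <- data.frame(
        male_id = mid[present], group_id = gid, event_id = ev$event_id[i],
        state = state[present])
      pct <- wc$mean[state[present]] + u_ev_w[i] + u_gr_w + u_ma_w[present] +
        rnorm(length(present), 0, wc$sd)
      w_post <- w_pre * (1 + pct / 100)
      weights_l[[length(weights_l) + 1L]] <- data.frame(
        male_id = rep(mid[present], 2L),
        date_day = rep(c(s0, e0), each = length(present)),
        grams = c(w_pre, w_post))

      if (runif(1) < tp$paternity$litter_prob) {
        total <- 1L + rpois(1, tp$paternity$mean_extra_pups)
        score <- tp$paternity$gcw * gcw / tp$scales$gcw["scale"] +
          tp$paternity$guard * (state[present] == "guard") +
          tp$paternity$sneaker * (state[present] == "sneaker") + u_ma_p[present]
        pr <- exp(score - max(score)); pr <- pr / sum(pr)
        sired <- drop(rmultinom(1, total, pr))
        pat_l[[length(pat_l) + 1L]] <- data.frame(
          male_id = mid[present], group_id = gid, event_id = ev$event_id[i],
          sired = sired, event_total = total)
      }

      last_event_end[present] <- e0
      if (i < nE) {
        dt <- ev$start_day[i + 1] - e0
        idata <- data.frame(origin_state = state[present], age = age,
                            age_rank = rk, gcw = gcw, interval_days = dt)
        p4 <- outcome_probs(tp, idata,
                            trans_re = matrix(u_ev_t[i, ], length(present), 2, byrow = TRUE) +
                              matrix(u_gr_t, length(present), 2, byrow = TRUE) +
                              u_ma_t[present, , drop = FALSE],
                            mort_re = u_ev_m[i] + u_gr_m + u_ma_m[present])
        u <- runif(length(present))
        outc <- STATES[1L + rowSums(u > t(apply(p4, 1, cumsum)))]
        died <- outc == "dead"
        death[present[died]] <- e0 + runif(sum(died), 0.1, 0.9) * dt
        state[present[!died]] <- outc[!died]
      }
    }

    observed <- which(!is.na(state))
    surv <- observed[is.na(death[observed])]
    death[surv] <- last_event_end[surv] + rexp(length(surv), 1 / 240)
    if (length(observed)) {
      males_l[[length(males_l) + 1L]] <- data.frame(
        male_id = mid[observed], group_id = gid,
        birth_day = birth[observed], death_day = death[observed])
      events_l[[length(events_l) + 1L]] <- data.frame(
        event_id = ev$event_id, group_id = gid,
        start_day = ev$start_day, end_day = ev$end_day)
    }
  }

  males <- do.call(rbind, males_l)
  keep <- males$male_id  # only males present in >= 1 event
  states <- do.call(rbind, states_l)
  weights <- do.call(rbind, weights_l)
  paternity <- if (length(pat_l)) do.call(rbind, pat_l) else
    data.frame(male_id = character(), group_id = character(), event_id = character(),
               sired = integer(), event_total = integer())
  states <- states[states$male_id %in% keep, ]
  weights <- weights[weights$male_id %in% keep, ]
  paternity <- paternity[paternity$male_id %in% keep, ]
  events <- do.call(rbind, events_l)[, c("event_id", "group_id", "start_day", "end_day")]
  rownames(males) <- rownames(states) <- rownames(weights) <- rownames(paternity) <-
    rownames(events) <- NULL

  structure(list(males = males, events = events, states = states,
                 paternity = paternity, weights = weights,
                 true_params = tp, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$males), "males,", nrow(x$events), "oestrus events,",
      nrow(x$states), "state records,", nrow(x$paternity), "paternity rows\n")
  invisible(x)
}

#' Simulate lifetime reproductive success directly from a ZINB law
#'
#' Standalone generator for validating the zero-inflated negative binomial
#' LRS model: covariates at first guarding are drawn on their standardized
#' scale, group random intercepts enter the count component, and counts are
#' drawn from the mixture `pi * delta_0 + (1 - pi) * NB(mu, phi)`.
#'
#' @param n number of males.
#' @param params the `lrs` component of [true_params()].
#' @param n_groups number of groups for the random intercept.
#' @param seed optional integer seed.
#' @return data.frame with `male_id`, `group_id`, `lrs`, `gcw`, `age_rank`
#'   (original scales).
#' @export
simulate_lrs <- function(n, params = true_params()$lrs, n_groups = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- sample.int(n_groups, n, replace = TRUE)
  u_g <- rnorm(n_groups, 0, params$sd_group)
  z_gcw <- rnorm(n, 0, 1)
  z_rank <- rnorm(n, 0, 1)
  eta <- params$mu_intercept + params$gcw * z_gcw + params$age_rank * z_rank + u_g[grp]
  pi0 <- plogis(params$zero_intercept)
  mu <- exp(eta)
  y <- ifelse(runif(n) < pi0, 0L, rnbinom(n, size = params$phi, mu = mu))
  data.frame(male_id = sprintf("M%04d", seq_len(n)),
             group_id = sprintf("G%02d", grp), lrs = y,
             gcw = z_gcw * 150, age_rank = pmax(1, round(4 + 3 * z_rank)))
}
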