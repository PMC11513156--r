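#' Summarize daily reproductive behaviour into one per-event state
#'
#' A male that guarded on any day of the oestrus event is a guard, unless he
#' more often used opportunistic sneaky tactics (strictly more sneak days
#' than guard days), in which case he is a sneaker. A male with no observed
#' reproductive activity on any day is an inactive subordinate. A tie between
#' guard and sneak days resolves to guard (guarding on any day is the
#' default).
#'
#' @param daily character vector of daily behaviours, each one of `"guard"`,
#'   `"sneak"`, `"none"`.
#' @return One of `"guard"`, `"sneaker"`, `"subordinate"`.
#' @examples
#' summarize_event_state(c("none", "none", "none"))   # subordinate
#' summarize_event_state(c("guard", "none", "none"))  # guard
#' summarize_event_state(c("sneak", "sneak", "guard"))# sneaker
#' @export
summarize_event_state <- function(daily) {
  if (length(daily) == 0) stop("at least one daily record is required")
  bad <- setdiff(daily, c("guard", "sneak", "none"))
  if (length(bad)) stop("unknown behaviour record: ", paste(bad, collapse = ", "))
  g <- sum(daily == "guard"); k <- sum(daily == "sneak")
  if (k > g && k >= 1) return("sneaker")
  if (g >= 1) return("guard")
  "subordinate"
}

#' Group-centred weight
#'
#' A male's weight minus the arithmetic mean weight of all adult male group
#' members at the same event (the focal male included), so within-group
#' centred weights sum to zero when all members are weighed.
#'
#' @param weight focal male's weight in grams.
#' @param group_weights weights of all adult male group members (including
#'   the focal male) at the event.
#' @return Centred weight in grams.
#' @examples
#' group_centred_weight(1500, c(1500, 1400, 1300))  # +100
#' @export
group_centred_weight <- function(weight, group_weights) {
  if (length(group_weights) == 0) stop("group_weights must be non-empty")
  if (any(group_weights <= 0) || any(weight <= 0)) stop("weights must be positive")
  weight - mean(group_weights)
}

#' Within-group age ranks (1 = oldest)
#'
#' Ranks males by age within a group at one event; rank 1 is the oldest. Ties
#' (e.g. littermates) are broken deterministically by lexicographic male id,
#' so ranks are always a permutation of `1..n`.
#'
#' @param ages ages in years.
#' @param ids male identifiers used for the tie-break (defaults to the
#'   element order).
#' @return Integer vector of ranks aligned with `ages`.
#' @examples
#' age_rank(c(8, 5, 2))          # 1 2 3
#' age_rank(c(4, 4), c("A","B")) # 1 2
#' @export
age_rank <- function(ages, ids = NULL) {
  if (length(ages) == 0) stop("ages must be non-empty")
  if (is.null(ids)) ids <- seq_along(ages)
  r <- integer(length(ages))
  r[order(-ages, ids)] <- seq_along(ages)
  r
}

#' Attach per-event covariates to state records
#'
#' Joins event dates and male birth dates onto the state table and derives
#' age (years at event start), body weight (most recent weight within a
#' lookback window before event start), group-centred weight and age rank.
#' Rows without a usable weight are dropped with a message.
#'
#' @param bundle a `cohort_bundle` (from [simulate_population()] or
#'   [read_bundle()]).
#' @param lookback maximum age of a weight record in days (default 30).
#' @return data.frame of state records with covariate columns `age`,
#'   `weight`, `gcw`, `age_rank`, `n_males`, plus event dates.
#' @export
event_covariates <- function(bundle, lookback = 30) {
  st <- merge(bundle$states, bundle$events[, c("event_id", "start_day", "end_day")],
              by = "event_id")
  st <- merge(st, bundle$males[, c("male_id", "birth_day", "death_day")], by = "male_id")
  if (any(st$start_day > st$death_day, na.rm = TRUE))
    stop("data-integrity error: state recorded after death")
  st$age <- (st$start_day - st$birth_day) / 365.25
  w <- merge(bundle$weights, st[, c("male_id", "event_id", "start_day")], by = "male_id")
  w <- w[w$date_day <= w$start_day & w$date_day >= w$start_day - lookback, ]
  w <- w[order(w$male_id, w$event_id, w$date_day), ]
  last <- !duplicated(w[, c("male_id", "event_id")], fromLast = TRUE)
  w <- w[last, c("male_id", "event_id", "grams")]
  n0 <- nrow(st)
  st <- merge(st, w, by = c("male_id", "event_id"))
  if (nrow(st) < n0)
    message(n0 - nrow(st), " state records dropped: no weight within ", lookback, " days")
  st$weight <- st$grams
  st <- st[order(st$event_id, st$male_id), ]
  st$gcw <- st$weight - ave(st$weight, st$event_id)
  st$age_rank <- NA_integer_
  for (ev in unique(st$event_id)) {
    i <- which(st$event_id == ev)
    st$age_rank[i] <- age_rank(st$age[i], st$male_id[i])
  }
  st$n_males <- ave(st$weight, st$event_id, FUN = length)
  rownames(st) <- NULL
  st[, c("male_id", "group_id", "event_id", "state", "start_day", "end_day",
         "birth_day", "death_day", "age", "weight", "gcw", "age_rank", "n_males")]
}

#' Build the transition table
#'
#' One observation per consecutive pair of oestrus events a male attended:
#' origin state, outcome (destination state, or death if the male died no
#' more than `max_death_gap` days after his last event and before the next
#' group event), covariates at the origin event, and the time to the next
#' oestrus event in days. Males attending fewer than two events contribute
#' nothing; terminal intervals whose death falls more than `max_death_gap`
#' days after the last attended event are dropped (earlier intervals are
#' kept), as are deaths after a group's final observed event (no next event
#' exists). The two filters are independent, hence order-independent.
#'
#' @param states_cov output of [event_covariates()].
#' @param events the bundle's events table.
#' @param max_death_gap inclusion window for terminal deaths, days (default
#'   365).
#' @param min_events minimum number of attended events for a male to enter
#'   the table (default 2, the study's rule). Note the default rule discards
#'   the whole record of males dying in their first interval, a
#'   length-biased selection that slightly deflates fitted subordinate
#'   mortality; `min_events = 1` removes that artifact and is what the
#'   parameter-recovery suite uses (see the methods vignette).
#' @return data.frame of transition observations; attributes
#'   `n_dropped_death_gap` and `n_dropped_no_next_event` count excluded
#'   terminal intervals.
#' @export
build_transition_table <- function(states_cov, events, max_death_gap = 365,
                                   min_events = 2) {
  events <- events[order(events$group_id, events$start_day), ]
  out <- vector("list", 256); n_out <- 0L
  dropped_gap <- 0L; dropped_no_next <- 0L
  for (m in unique(states_cov$male_id)) {
    rows <- states_cov[states_cov$male_id == m, ]
    rows <- rows[order(rows$start_day), ]
    if (nrow(rows) < min_events) {
      # singular-event males are excluded from transition analysis entirely
      next
    }
    obs <- if (nrow(rows) < 2) NULL else data.frame(
      male_id = m, group_id = rows$group_id[-nrow(rows)],
      event_from = rows$event_id[-nrow(rows)], event_to = rows$event_id[-1],
      origin_state = rows$state[-nrow(rows)], outcome = rows$state[-1],
      age = rows$age[-nrow(rows)], age_rank = rows$age_rank[-nrow(rows)],
      gcw = rows$gcw[-nrow(rows)], weight = rows$weight[-nrow(rows)],
      interval_days = rows$start_day[-1] - rows$end_day[-nrow(rows)])
    if (!is.null(obs)) { n_out <- n_out + 1L; out[[n_out]] <- obs }
    # terminal interval: death after the last attended event
    lastr <- rows[nrow(rows), ]
    if (!is.na(lastr$death_day)) {
      nxt <- events[events$group_id == lastr$group_id &
                      events$start_day > lastr$end_day, , drop = FALSE]
      if (nrow(nxt) == 0) {
        dropped_no_next <- dropped_no_next + 1L
      } else if (lastr$death_day - lastr$end_day > max_death_gap) {
        dropped_gap <- dropped_gap + 1L
      } else if (lastr$death_day <= nxt$start_day[1]) {
        n_out <- n_out + 1L
        out[[n_out]] <- data.frame(
          male_id = m, group_id = lastr$group_id,
          event_from = lastr$event_id, event_to = NA_character_,
          origin_state = lastr$state, outcome = "dead",
          age = lastr$age, age_rank = lastr$age_rank,
          gcw = lastr$gcw, weight = lastr$weight,
          interval_days = nxt$start_day[1] - lastr$end_day)
      } else {
        dropped_gap <- dropped_gap + 1L  # outlived the next event unobserved
      }
    }
  }
  res <- if (n_out) do.call(rbind, out[seq_len(n_out)]) else
    data.frame(male_id = character(), group_id = character(),
               event_from = character(), event_to = character(),
               origin_state = character(), outcome = character(),
               age = numeric(), age_rank = integer(), gcw = numeric(),
               weight = numeric(), interval_days = numeric())
  rownames(res) <- NULL
  attr(res, "n_dropped_death_gap") <- dropped_gap
  attr(res, "n_dropped_no_next_event") <- dropped_no_next
  res
}

#' Link litters to the oestrus events that conceived them
#'
#' Gestation is around nine weeks: a litter links to the event of its group
#' whose end date lies `window` days (default 44-74, i.e. 59 +/- 15) before
#' the litter birth date; when two events fall in the window the one nearest
#' 59 days wins. Litters with no event in the window stay unlinked and are
#' reported via a message.
#'
#' @param litters data.frame with `litter_id`, `group_id`, `birth_day`.
#' @param events events table with `event_id`, `group_id`, `end_day`.
#' @param window numeric length-2 inclusion window in days.
#' @param target gestation gap the tie-break targets (days).
#' @return `litters` with an `event_id` column (`NA` when unlinked).
#' @export
link_litters_to_events <- function(litters, events, window = c(44, 74), target = 59) {
  litters$event_id <- NA_character_
  for (i in seq_len(nrow(litters))) {
    cand <- events[events$group_id == litters$group_id[i], ]
    gap <- litters$birth_day[i] - cand$end_day
    ok <- which(gap >= window[1] & gap <= window[2])
    if (length(ok)) litters$event_id[i] <- cand$event_id[ok[which.min(abs(gap[ok] - target))]]
  }
  if (anyNA(litters$event_id))
    message(sum(is.na(litters$event_id)), " litter(s) could not be linked to an oestrus event")
  litters
}

#' Pairwise collinearity report for model covariates
#'
#' Pearson correlations for all covariate pairs, flagged above a threshold.
#' Constant columns yield an undefined correlation, reported as `NA`.
#'
#' @param data design table.
#' @param covariates character vector of numeric columns (default: age, age
#'   rank, group-centred weight).
#' @param threshold absolute correlation that triggers a flag (default 0.7).
#' @return data.frame with `cov1`, `cov2`, `r`, `flagged`.
#' @export
diagnose_collinearity <- function(data, covariates = c("age", "age_rank", "gcw"),
                                  threshold = 0.7) {
  if (nrow(data) < 3) stop("need at least 3 rows")
  prs <- utils::combn(covariates, 2)
  r <- apply(prs, 2, function(p) {
    x <- data[[p[1]]]; y <- data[[p[2]]]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  })
  data.frame(cov1 = prs[1, ], cov2 = prs[2, ], r = r,
             flagged = !is.na(r) & abs(r) >= threshold)
}

#' Derive all model-ready design tables from a cohort bundle
#'
#' Runs [event_covariates()] and [build_transition_table()] and assembles the
#' paternity, weight-change and lifetime-reproductive-success design tables
#' used by the fitting functions.
#'
#' @inheritParams event_covariates
#' @param max_death_gap,min_events see [build_transition_table()].
#' @return A list of class `cohort_design` with elements `transitions`,
#'   `paternity`, `weight_change`, `lrs`, `states_cov`, `collinearity`.
#' @export
preprocess_cohort <- function(bundle, lookback = 30, max_death_gap = 365,
                              min_events = 2) {
  sc <- event_covariates(bundle, lookback = lookback)
  transitions <- build_transition_table(sc, bundle$events,
                                        max_death_gap = max_death_gap,
                                        min_events = min_events)

  pat <- merge(bundle$paternity,
               sc[, c("male_id", "event_id", "age", "age_rank", "gcw", "weight")],
               by = c("male_id", "event_id"))

  wc <- weight_change_design(bundle, sc)

  lrs <- lrs_design(bundle, sc)

  structure(list(transitions = transitions, paternity = pat, weight_change = wc,
                 lrs = lrs, states_cov = sc,
                 collinearity = diagnose_collinearity(transitions)),
            class = "cohort_design")
}

# percentage weight change over each oestrus event, subordinate vs guard
weight_change_design <- function(bundle, states_cov) {
  sc <- states_cov[states_cov$state %in% c("subordinate", "guard"), ]
  sc$.row <- seq_len(nrow(sc))
  w <- merge(bundle$weights, sc[, c("male_id", "event_id", "start_day", "end_day", ".row")],
             by = "male_id")
  w <- w[w$date_day > w$start_day & w$date_day <= w$end_day + 7, ]
  w <- w[order(w$.row, w$date_day), ]
  w <- w[!duplicated(w$.row), ]  # first post-oestrus weight per state record
  post <- rep(NA_real_, nrow(sc)); post[w$.row] <- w$grams
  ok <- !is.na(post)
  data.frame(male_id = sc$male_id[ok], group_id = sc$group_id[ok],
             event_id = sc$event_id[ok], state = sc$state[ok],
             pct_change = 100 * (post[ok] - sc$weight[ok]) / sc$weight[ok])
}

# LRS with covariates at first guarding; one row per male ever observed guarding
lrs_design <- function(bundle, states_cov) {
  sired <- if (nrow(bundle$paternity)) {
    aggregate(sired ~ male_id, data = bundle$paternity, FUN = sum)
  } else {
    data.frame(male_id = character(), sired = integer())
  }
  g <- states_cov[states_cov$state == "guard", ]
  g <- g[order(g$male_id, g$start_day), ]
  first <- g[!duplicated(g$male_id), ]
  lrs <- merge(first[, c("male_id", "group_id", "age", "age_rank", "gcw", "weight")],
               sired, by = "male_id", all.x = TRUE)
  lrs$lrs <- ifelse(is.na(lrs$sired), 0L, lrs$sired)
  lrs$sired <- NULL
  lrs
}
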