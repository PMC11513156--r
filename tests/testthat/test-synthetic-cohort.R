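test_that("growth curve hits its boundary, plateau and linear-decline contracts", {
  g <- true_params()$growth
  expect_equal(growth_curve(0, g), g$neonate)
  # plateau set to 1456 g: curve maximum within 1 g of the plateau
  expect_lt(abs(max(growth_curve(seq(0, 12, 0.01), g)) - 1456), 1)
  # pure linear decline after onset: age 10 vs age 8 at 25 g/yr is -50 g
  expect_equal(growth_curve(10, g) - growth_curve(8, g), -50)
  # monotone up to the senescence onset
  expect_true(all(diff(growth_curve(seq(0, g$senescence_onset, 0.05), g)) > 0))
  expect_error(growth_curve(-1, g), "age")
})

test_that("event schedules are ordered, non-overlapping and correctly spaced", {
  set.seed(1)
  ev <- schedule_events(1, 4, jitter = 0)
  expect_equal(nrow(ev), 4)
  expect_approx(diff(ev$start_day), rep(365.25 / 4, 3), tol = 1e-9)
  # tiny window: no events, and never an overlap in jittered schedules
  expect_equal(nrow(schedule_events(0.1, 4, jitter = 0)), 0)
  for (s in 1:5) {
    set.seed(s)
    e <- schedule_events(5, 4, jitter = 0.4)
    expect_true(all(diff(e$start_day) > 0))
    expect_true(all(e$start_day[-1] >= e$end_day[-nrow(e)]))
  }
  # law of large numbers: mean start-to-start gap near 1/events_per_year
  set.seed(2)
  big <- schedule_events(10000, 4, jitter = 0.2)
  expect_lt(abs(mean(diff(big$start_day)) - 365.25 / 4) / (365.25 / 4), 0.05)
})

test_that("interval outcome probabilities sum to one across a covariate grid", {
  tp <- tiny_params()
  grid <- expand.grid(origin_state = c("subordinate", "sneaker", "guard"),
                      age = c(1, 5, 9), age_rank = c(1, 6), gcw = c(-300, 0, 300),
                      interval_days = c(60, 120), stringsAsFactors = FALSE)
  p <- outcome_probs(tp, grid)
  expect_true(all(p >= 0 & p <= 1))
  expect_approx(rowSums(p), rep(1, nrow(grid)), tol = 1e-12)
})

test_that("empirical transition frequencies match the generative law within 3 SE", {
  tp <- tiny_params()
  grid <- expand.grid(origin_state = c("subordinate", "guard"),
                      age = c(2, 6.5), gcw = c(-200, 200), age_rank = 4,
                      interval_days = 91, stringsAsFactors = FALSE)
  n_rep <- 12500  # 8 cells x 12500 = 100 000 intervals
  d <- grid[rep(seq_len(nrow(grid)), each = n_rep), ]
  out <- simulate_transitions(tp, d, seed = 31)
  p_theory <- outcome_probs(tp, grid)
  for (cell in seq_len(nrow(grid))) {
    oc <- out[(cell - 1) * n_rep + seq_len(n_rep)]
    for (st in STATES) {
      phat <- mean(oc == st)
      p0 <- p_theory[cell, st]
      se <- sqrt(p0 * (1 - p0) / n_rep)
      expect_lt(abs(phat - p0), 3 * se + 1e-12)
    }
  }
})

test_that("a strongly negative guard weight-mortality slope shows up in raw death fractions", {
  tp <- tiny_params()
  tp$mortality$beta["gcw:oG"] <- -1.5
  d <- data.frame(origin_state = "guard", age = 5, age_rank = 3,
                  gcw = rep(c(-200, 200), each = 5000), interval_days = 91)
  out <- simulate_transitions(tp, d, seed = 7)
  below <- mean(out[1:5000] == "dead")
  above <- mean(out[5001:10000] == "dead")
  expect_gt(below, above)
})

test_that("simulated bundles are deterministic and death is absorbing", {
  cfg <- sim_config(n_groups = 3, years = 5, seed = 99)
  b1 <- simulate_population(cfg)
  b2 <- simulate_population(cfg)
  d1 <- file.path(tempdir(), "bundle_a"); d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in c("males.csv", "events.csv", "states.csv", "paternity.csv", "weights.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  # no state record after a male's death date
  st <- merge(b1$states, b1$events[, c("event_id", "start_day")], by = "event_id")
  st <- merge(st, b1$males[, c("male_id", "death_day")], by = "male_id")
  expect_true(all(is.na(st$death_day) | st$start_day <= st$death_day))
  # every exported male appears in at least one event
  expect_true(all(b1$males$male_id %in% b1$states$male_id))
  # paternity totals equal the sum of per-male sired counts
  if (nrow(b1$paternity)) {
    tot <- aggregate(sired ~ event_id + event_total, data = b1$paternity, FUN = sum)
    expect_equal(tot$sired, tot$event_total)
  }
})

test_that("with death probability zero no male dies before his last scheduled event", {
  tp <- tiny_params()
  tp$mortality$beta[c("oS", "oK", "oG")] <- -1e6  # death probability 0
  cfg <- sim_config(n_groups = 2, years = 4, seed = 5, true_params = tp)
  b <- simulate_population(cfg)
  d <- suppressMessages(preprocess_cohort(b))
  expect_true(all(d$transitions$outcome != "dead"))
  # every male is present at every group event from maturity to study end
  last_ev <- aggregate(start_day ~ group_id, data = b$events, FUN = max)
  for (g in last_ev$group_id) {
    males_g <- b$males[b$males$group_id == g, ]
    expect_true(all(males_g$death_day > last_ev$start_day[last_ev$group_id == g]))
  }
})

test_that("bundle round-trips through CSV with dates and states intact", {
  cfg <- sim_config(n_groups = 2, years = 3, seed = 17)
  b <- simulate_population(cfg)
  dir <- file.path(tempdir(), "bundle_rt")
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$males$male_id, b$males$male_id)
  expect_equal(sort(unique(b2$states$state)),
               sort(unique(b$states$state)))
  expect_equal(b2$events$start_day, round(b$events$start_day))
  expect_equal(b2$true_params$transition$beta, b$true_params$transition$beta)
  expect_equal(b2$true_params$mortality$beta, b$true_params$mortality$beta)
  # invalid configs are rejected before any work
  expect_error(sim_config(n_groups = 0), "n_groups")
  expect_error(sim_config(years = -1), "years")
})
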