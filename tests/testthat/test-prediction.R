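# build a small posterior_draws object by hand around known draws
fake_transition_fit <- function(draws_by_param, variant = "quadratic_age") {
  nm <- names(draws_by_param)
  nd <- length(draws_by_param[[1]])
  arr <- array(NA_real_, c(nd / 2, 2, length(nm)), dimnames = list(NULL, NULL, nm))
  for (j in seq_along(nm)) arr[, , j] <- draws_by_param[[j]]
  structure(list(
    draws = arr,
    spec = model_spec("transition", variant = variant, share_slopes = TRUE,
                      chains = 2, iterations = 40, burn_in = 20, thinning = 1),
    scaler = fixed_scaler(),
    rhat = setNames(rep(1, length(nm)), nm),
    summary = NULL, n_obs = 0,
    data_means = c(gcw = 0, age = 5),
    support = list(gcw = c(-400, 400), age = c(1, 11))
  ), class = "posterior_draws")
}

trans_par_names <- function() {
  cols <- c("oS", "oK", "oG", "gcw", "age", "age2")
  c(paste0("sneaker:", cols), paste0("guard:", cols))
}

test_that("a degenerate posterior gives zero-width ribbons equal to the point value", {
  nm <- trans_par_names()
  vals <- setNames(as.list(rep(0.4, length(nm))), nm)
  draws <- lapply(vals, function(v) rep(v, 40))
  fit <- fake_transition_fit(draws)
  cv <- predict_curve(fit, "gcw", c(-100, 0, 100), origin = "subordinate",
                      destination = "guard")
  expect_equal(cv$lower, cv$mean)
  expect_equal(cv$upper, cv$mean)
})

test_that("symmetric-null draws give a flat curve at 1/3 and match a per-draw oracle", {
  nm <- trans_par_names()
  draws0 <- setNames(lapply(nm, function(x) rep(0, 40)), nm)
  fit0 <- fake_transition_fit(draws0)
  cv0 <- predict_curve(fit0, "gcw", seq(-200, 200, 100))
  expect_approx(cv0$mean, rep(1 / 3, 5), 1e-12)

  set.seed(77)
  draws <- setNames(lapply(nm, function(x) rnorm(40, 0, 0.7)), nm)
  fit <- fake_transition_fit(draws)
  grid <- c(-150, 0, 150)
  cv <- predict_curve(fit, "gcw", grid, origin = "subordinate", destination = "guard")
  # independent oracle: loop over draws explicitly
  for (g in seq_along(grid)) {
    z_gcw <- grid[g] / 150; z_age <- 0  # reference age = 5 = scaler centre
    per_draw <- vapply(1:40, function(i) {
      eta_k <- draws[["sneaker:oS"]][i] + draws[["sneaker:gcw"]][i] * z_gcw
      eta_g <- draws[["guard:oS"]][i] + draws[["guard:gcw"]][i] * z_gcw
      oracle_softmax_row(eta_k, eta_g)[["guard"]]
    }, numeric(1))
    expect_approx(cv$mean[g], mean(per_draw), 1e-10)
    expect_approx(cv$lower[g], unname(quantile(per_draw, 0.025)), 1e-10)
    expect_approx(cv$upper[g], unname(quantile(per_draw, 0.975)), 1e-10)
  }
  expect_true(all(cv$lower <= cv$mean & cv$mean <= cv$upper))
})

test_that("prediction warns on extrapolation and on unconverged parameters", {
  nm <- trans_par_names()
  draws0 <- setNames(lapply(nm, function(x) rnorm(40, 0, 0.3)), nm)
  fit <- fake_transition_fit(draws0)
  expect_warning(predict_curve(fit, "gcw", c(-1000, 0)), "support")
  fit$rhat["guard:gcw"] <- 1.5
  expect_warning(predict_curve(fit, "gcw", c(-100, 0)), "R-hat")
  expect_error(predict_curve(fit, "body_length", c(1, 2)), "unknown covariate")
})

test_that("transition-matrix composition holds per draw at any grid point", {
  set.seed(31)
  tp <- tiny_params()
  for (i in 1:5) {
    tb <- tp$transition$beta; tb[] <- tb + rnorm(length(tb), 0, 0.3)
    mb <- tp$mortality$beta; mb[] <- mb + rnorm(length(mb), 0, 0.3)
    cv <- list(age = runif(1, 1, 11), age_rank = 3, gcw = rnorm(1, 0, 200),
               interval_days = 91)
    m <- transition_matrix_at(tb, mb, cv, fixed_scaler())
    expect_approx(sum(m["subordinate", ]), 1, 1e-10)
  }
})

test_that("raw mortality summary reproduces known contingency fixtures", {
  mk <- function(state, gcw, n, deaths) data.frame(
    origin_state = rep(state, n), gcw = rep(gcw, n),
    outcome = rep(c("dead", state), c(deaths, n - deaths)))
  tab <- summarize_raw_mortality(rbind(
    mk("guard", -50, 200, 29), mk("guard", 50, 908, 2),
    mk("subordinate", -50, 1190, 80), mk("subordinate", 50, 976, 80),
    mk("sneaker", -10, 30, 3)))
  get <- function(st, wc) tab$percent[tab$state == st & tab$weight_class == wc]
  expect_equal(get("guard", "below_average"), 14.5)
  expect_equal(get("subordinate", "below_average"), 6.7)
  expect_equal(get("subordinate", "average_and_above"), 8.2)
  expect_equal(attr(tab, "n_sneaker_excluded"), 30)
  # percentages recompute exactly from their own numerator/denominator
  expect_equal(tab$percent, round(100 * tab$deaths / tab$totals, 1))
  # gcw = 0 counts as average-and-above
  tab2 <- summarize_raw_mortality(mk("guard", 0, 10, 1))
  expect_equal(tab2$totals[tab2$state == "guard" &
                             tab2$weight_class == "average_and_above"], 10)
  # empty cells report NA, not 0
  expect_true(is.na(tab2$percent[tab2$state == "subordinate" &
                                   tab2$weight_class == "below_average"]))
})

test_that("quadratic switch points back-transform and warn without an interior maximum", {
  nm <- trans_par_names()
  draws <- setNames(lapply(nm, function(x) rep(0, 40)), nm)
  # raw-scale check: identity scaler, b1 = 2, b2 = -1 -> peak at 1.0
  draws[["guard:age"]] <- rep(2, 40)
  draws[["guard:age2"]] <- rep(-1, 40)
  fit <- fake_transition_fit(draws)
  fit$scaler <- new_scaler(centre = c(age = 0, gcw = 0), scale = c(age = 1, gcw = 1),
                           method = c(age = "identity", gcw = "identity"))
  sp <- quadratic_switch_point(fit)
  expect_equal(sp$mean, 1.0)
  expect_false(sp$boundary)
  # standardized scale: peak at z = 0.6 -> age 6.5 under the generator scaler
  draws[["guard:age"]] <- rep(0.96, 40)
  draws[["guard:age2"]] <- rep(-0.8, 40)
  fit2 <- fake_transition_fit(draws)
  sp2 <- quadratic_switch_point(fit2)
  expect_approx(sp2$mean, 6.5, 1e-9)
  # all-positive quadratic terms: boundary + warning
  draws[["guard:age2"]] <- rep(0.5, 40)
  fit3 <- fake_transition_fit(draws)
  expect_warning(sp3 <- quadratic_switch_point(fit3), "boundary|negative")
  expect_true(sp3$boundary)
})

test_that("reports are complete, deterministic, and fail with no fits", {
  expect_error(render_report(list(), out_dir = tempdir()), "no fitted models")
  d <- tiny_transitions(80, seed = 8)
  fit <- suppressWarnings(
    fit_transition(d, variant = "quadratic_age", share_slopes = TRUE, chains = 2,
                   iterations = 500, burn_in = 200, thinning = 2, seed = 3,
                   scaler = fixed_scaler()))
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  f1 <- suppressWarnings(render_report(list(trans = fit), transitions = d, out_dir = out1))
  f2 <- suppressWarnings(render_report(list(trans = fit), transitions = d, out_dir = out2))
  expect_true(file.exists(file.path(out1, "curves", "gain_guard_vs_gcw.csv")))
  expect_true(file.exists(file.path(out1, "curves", "lose_guard_vs_gcw.csv")))
  expect_true(file.exists(file.path(out1, "raw_mortality.csv")))
  for (f in c("params_trans.csv", "raw_mortality.csv", "report.md",
              file.path("curves", "gain_guard_vs_gcw.csv"))) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
})
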