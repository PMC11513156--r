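sc <- fixed_scaler()

test_that("transition log-likelihood matches a brute-force softmax oracle", {
  d <- tiny_transitions(12)
  d <- d[d$outcome != "dead", ]
  tp <- tiny_params()
  beta <- tp$transition$beta
  # independent oracle: explicit per-row softmax on hand-built predictors
  z_age <- (d$age - 5) / 2.5
  z_gcw <- d$gcw / 150
  oracle <- 0
  for (i in seq_len(nrow(d))) {
    ints <- c(subordinate = "oS", sneaker = "oK", guard = "oG")[[d$origin_state[i]]]
    eta_k <- beta[ints, "sneaker"] + beta["gcw", "sneaker"] * z_gcw[i] +
      beta["age", "sneaker"] * z_age[i] + beta["age2", "sneaker"] * z_age[i]^2
    eta_g <- beta[ints, "guard"] + beta["gcw", "guard"] * z_gcw[i] +
      beta["age", "guard"] * z_age[i] + beta["age2", "guard"] * z_age[i]^2
    p <- oracle_softmax_row(eta_k, eta_g)
    oracle <- oracle + log(p[[d$outcome[i]]])
  }
  expect_approx(transition_loglik(beta, d, sc, "quadratic_age", TRUE), oracle, 1e-10)
})

test_that("transition log-likelihood limits: symmetric null and saturation", {
  d <- tiny_transitions(9)
  d <- d[d$outcome != "dead", ]
  beta0 <- matrix(0, 6, 2, dimnames = list(c("oS", "oK", "oG", "gcw", "age", "age2"),
                                           c("sneaker", "guard")))
  expect_approx(transition_loglik(beta0, d, sc, "quadratic_age", TRUE),
                nrow(d) * log(1 / 3), 1e-10)
  # near-saturated guard destination: probability -> 1, loglik -> 0-
  d1 <- data.frame(origin_state = "subordinate", outcome = "guard",
                   age = 5, age_rank = 3, gcw = 0, interval_days = 91)
  bsat <- beta0; bsat["oS", "guard"] <- 30
  ll <- transition_loglik(bsat, d1, sc, "quadratic_age", TRUE)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-10)
  d_dead <- data.frame(origin_state = "guard", outcome = "dead", age = 5,
                       age_rank = 2, gcw = 0, interval_days = 91)
  expect_error(transition_loglik(beta0, d_dead, sc, "quadratic_age", TRUE), "dead")
})

test_that("mortality log-likelihood matches a brute-force Bernoulli oracle", {
  d <- tiny_transitions(10)
  tp <- tiny_params()
  beta <- tp$mortality$beta
  z_age <- (d$age - 5) / 2.5
  z_gcw <- d$gcw / 150
  z_dt <- (d$interval_days - 91) / 30
  oracle <- 0
  for (i in seq_len(nrow(d))) {
    st <- d$origin_state[i]
    eta <- beta[[c(subordinate = "oS", sneaker = "oK", guard = "oG")[[st]]]] +
      beta[[paste0("gcw:", c(subordinate = "oS", sneaker = "oK", guard = "oG")[[st]])]] * z_gcw[i] +
      beta[["age"]] * z_age[i] + beta[["age2"]] * z_age[i]^2 + beta[["interval_days"]] * z_dt[i]
    p <- 1 / (1 + exp(-eta))
    oracle <- oracle + if (d$outcome[i] == "dead") log(p) else log(1 - p)
  }
  expect_approx(mortality_loglik(beta, d, sc, "quadratic_age"), oracle, 1e-10)
  # all parameters zero: p = 0.5 everywhere
  b0 <- setNames(rep(0, length(beta)), names(beta))
  expect_approx(mortality_loglik(b0, d, sc, "quadratic_age"),
                nrow(d) * log(0.5), 1e-10)
  # intercepts -> -Inf-ish: survival certain, loglik of all-survivor data -> 0
  d_live <- d[d$outcome != "dead", ]
  bneg <- b0; bneg[c("oS", "oK", "oG")] <- -50
  expect_gt(mortality_loglik(bneg, d_live, sc, "quadratic_age"), -1e-8)
  d_bad <- d; d_bad$interval_days[1] <- -2
  expect_error(mortality_loglik(beta, d_bad, sc, "quadratic_age"), "interval_days")
})

test_that("binomial paternity log-likelihood matches dbinom and closed forms", {
  set.seed(8)
  d <- data.frame(sired = c(1, 0, 2, 3, 1, 0, 2, 1),
                  event_total = c(2, 3, 4, 5, 2, 1, 3, 4),
                  gcw = rnorm(8, 0, 150), age_rank = sample(1:6, 8, TRUE),
                  male_id = letters[1:8], group_id = "G1", event_id = "E1")
  beta <- c("(Intercept)" = 0.3, gcw = 0.5, age_rank = -0.2)
  z_gcw <- d$gcw / 150; z_rk <- (d$age_rank - 4) / 3
  oracle <- 0
  for (i in 1:8) {
    p <- plogis(0.3 + 0.5 * z_gcw[i] - 0.2 * z_rk[i])
    oracle <- oracle + log(choose(d$event_total[i], d$sired[i]) *
                             p^d$sired[i] * (1 - p)^(d$event_total[i] - d$sired[i]))
  }
  expect_approx(paternity_loglik(beta, d, sc, "age_rank"), oracle, 1e-10)
  # params 0, sired = total/2 with n = 2: pmf = C(2,1) * 0.25 = 0.5 per row
  d2 <- data.frame(sired = 1, event_total = 2, gcw = 0, age_rank = 4)
  b0 <- c("(Intercept)" = 0, gcw = 0, age_rank = 0)
  expect_approx(paternity_loglik(b0, d2, sc, "age_rank"), log(0.5), 1e-12)
  # saturation: p -> 1 with all successes
  bsat <- c("(Intercept)" = 40, gcw = 0, age_rank = 0)
  d3 <- data.frame(sired = 3, event_total = 3, gcw = 0, age_rank = 4)
  expect_gt(paternity_loglik(bsat, d3, sc, "age_rank"), -1e-10)
  d_bad <- d; d_bad$sired[1] <- 10
  expect_error(paternity_loglik(beta, d_bad, sc, "age_rank"), "sired")
})

test_that("Gaussian weight-change log-likelihood matches a dnorm oracle", {
  set.seed(9)
  d <- data.frame(state = rep(c("subordinate", "guard"), 5),
                  pct_change = rnorm(10, -1, 2))
  beta <- c("(Intercept)" = 0.2, state_guard = -2.5)
  oracle <- 0
  for (i in 1:10) {
    mu <- 0.2 - 2.5 * (d$state[i] == "guard")
    oracle <- oracle + (-0.5 * log(2 * pi * 1.7^2) -
                          (d$pct_change[i] - mu)^2 / (2 * 1.7^2))
  }
  expect_approx(gaussian_loglik(beta, 1.7, d), oracle, 1e-10)
  expect_error(gaussian_loglik(beta, 0, d), "sigma")
})

test_that("ZINB log pmf: degenerate mixtures, series oracle, normalization and mean", {
  # pi = 1: all mass at zero
  expect_equal(exp(zinb_logpmf(0, 1, 3, 1.5)), 1)
  expect_equal(exp(zinb_logpmf(4, 1, 3, 1.5)), 0)
  # pi = 0 reduces to the plain NB pmf; independent lgamma series oracle
  k <- 0:15; mu <- 2.7; phi <- 1.3
  oracle <- lgamma(k + phi) - lgamma(phi) - lfactorial(k) +
    phi * log(phi / (phi + mu)) + k * log(mu / (phi + mu))
  expect_approx(zinb_logpmf(k, 0, mu, phi), oracle, 1e-10)
  # normalization and mean identity over a (pi, mu, phi) grid
  for (pi0 in c(0, 0.3, 0.8)) for (mu in c(0.5, 3, 20)) for (phi in c(0.4, 1, 5)) {
    kk <- 0:10000
    p <- exp(zinb_logpmf(kk, pi0, mu, phi))
    expect_gt(sum(p), 1 - 1e-8)
    expect_lt(abs(sum(kk * p) - (1 - pi0) * mu), 1e-6)
  }
  expect_error(zinb_logpmf(-1, 0.5, 1, 1), "k")
  expect_error(zinb_logpmf(1, 1.5, 1, 1), "pi")
})

test_that("random-effect terms enter the likelihoods additively", {
  d <- tiny_transitions(8)
  tp <- tiny_params()
  re <- list(male = setNames(rnorm(5, 0, 0.5), sprintf("M%02d", 1:5)))
  ll0 <- mortality_loglik(tp$mortality$beta, d, sc, "quadratic_age")
  ll1 <- mortality_loglik(tp$mortality$beta, d, sc, "quadratic_age", re = re)
  expect_false(isTRUE(all.equal(ll0, ll1)))
  # zero random effects are a no-op
  re0 <- list(male = setNames(rep(0, 5), sprintf("M%02d", 1:5)))
  expect_approx(mortality_loglik(tp$mortality$beta, d, sc, "quadratic_age", re = re0),
                ll0, 1e-12)
})
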