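# Shared fixtures: small worlds and covariate tables built in code.

tiny_params <- function(variant = "quadratic_age") true_params(variant)

# a small transition-observation table with both live and dead outcomes
tiny_transitions <- function(n = 12, seed = 421, variant = "quadratic_age") {
  set.seed(seed)
  tp <- tiny_params(variant)
  d <- data.frame(
    origin_state = sample(c("subordinate", "guard", "sneaker"), n, TRUE, c(.6, .3, .1)),
    age = runif(n, 1, 11),
    age_rank = sample(1:8, n, TRUE),
    gcw = rnorm(n, 0, 150),
    interval_days = runif(n, 60, 130),
    male_id = sprintf("M%02d", sample(5, n, TRUE)),
    group_id = sprintf("G%01d", sample(2, n, TRUE)),
    event_from = sprintf("E%02d", sample(6, n, TRUE)))
  d$outcome <- simulate_transitions(tp, d, seed = seed)
  d
}

# brute-force per-row softmax, written independently of the package path
oracle_softmax_row <- function(eta_k, eta_g) {
  den <- 1 + exp(eta_k) + exp(eta_g)
  c(subordinate = 1 / den, sneaker = exp(eta_k) / den, guard = exp(eta_g) / den)
}

fixed_scaler <- function() scaler_from_params(true_params())

expect_approx <- function(x, y, tol = 1e-10) expect_lt(max(abs(x - y)), tol)
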