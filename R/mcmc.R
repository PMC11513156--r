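#' Specify a Bayesian model fit
#'
#' Collects the model family, covariate variant, random-effect structure,
#' priors and MCMC settings. Chain-length defaults mirror the motivating
#' analysis: mortality runs 50 000 iterations (burn-in 5000), all other
#' models 20 000 (burn-in 2000), thinning 100, 3 chains. Priors: fixed
#' effects Normal(0, 2.5^2) on the standardized covariate scale;
#' random-effect SDs half-Normal(0, 1); Gaussian residual SD half-Normal(0,
#' 5); ZINB log-dispersion Normal(0, 1.5^2). All are overridable.
#'
#' @param model one of `"transition"`, `"mortality"`, `"paternity"`,
#'   `"weight_change"`, `"lrs"`.
#' @param variant `"age_rank"` or `"quadratic_age"` (for `"lrs"`:
#'   `"relative"` or `"absolute"`).
#' @param share_slopes transition model only: share covariate slopes across
#'   origin states (default `FALSE`, origin-specific slopes).
#' @param time_interactions mortality only: include interval-by-covariate
#'   interactions (default `FALSE`; none proved credible in the motivating
#'   analysis).
#' @param random_effects subset of `c("event", "group", "male")`.
#' @param chains number of chains (>= 2, required by the R-hat diagnostic).
#' @param iterations,burn_in,thinning MCMC settings; `iterations` counts all
#'   iterations including burn-in.
#' @param prior named list overriding any of `beta_mean`, `beta_sd`,
#'   `re_sd_scale`, `sigma_scale`, `logphi_sd`.
#' @param seed integer seed for chain initialization.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model = c("transition", "mortality", "paternity",
                                 "weight_change", "lrs"),
                       variant = NULL, share_slopes = FALSE,
                       time_interactions = FALSE,
                       random_effects = c("event", "group", "male"),
                       chains = 3, iterations = NULL, burn_in = NULL,
                       thinning = 100, prior = list(), seed = 1L) {
  model <- match.arg(model)
  if (is.null(variant)) variant <- if (model == "lrs") "relative" else "age_rank"
  ok_var <- if (model == "lrs") c("relative", "absolute")
            else if (model == "weight_change") "none"
            else c("age_rank", "quadratic_age")
  if (model == "weight_change") variant <- "none"
  if (!variant %in% ok_var)
    stop("variant for model '", model, "' must be one of: ", paste(ok_var, collapse = ", "))
  if (model == "lrs") random_effects <- "group"
  if (chains < 2) stop("chains must be >= 2 (split R-hat needs at least two chains)")
  if (is.null(iterations)) iterations <- if (model == "mortality") 50000L else 20000L
  if (is.null(burn_in)) burn_in <- if (model == "mortality") 5000L else 2000L
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (thinning < 1) stop("thinning must be >= 1")
  pr <- list(beta_mean = 0, beta_sd = 2.5, re_sd_scale = 1,
             sigma_scale = 5, logphi_sd = 1.5)
  bad <- setdiff(names(prior), names(pr))
  if (length(bad)) stop("unknown prior settings: ", paste(bad, collapse = ", "))
  pr[names(prior)] <- prior
  structure(list(model = model, variant = variant, share_slopes = share_slopes,
                 time_interactions = time_interactions,
                 random_effects = random_effects, chains = as.integer(chains),
                 iterations = as.integer(iterations), burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), prior = pr,
                 seed = as.integer(seed)), class = "model_spec")
}

# which original-scale covariates the design needs, for scaler fitting
spec_covariates <- function(spec) {
  at <- if (spec$variant == "quadratic_age") "age" else
        if (spec$variant == "age_rank") "age_rank" else character()
  switch(spec$model,
    transition = c("gcw", at),
    mortality = c("gcw", at, "interval_days"),
    paternity = c("gcw", at),
    weight_change = character(),
    lrs = if (spec$variant == "relative") c("gcw", "age_rank") else c("weight", "age"))
}

# model-specific input contracts, checked before any scaler fitting
validate_fit_data <- function(spec, data) {
  if (!nrow(data)) stop("design table is empty")
  switch(spec$model,
    transition = if (!any(data$outcome != "dead"))
      stop("no survivor transitions in data"),
    mortality = if (any(data$interval_days < 0))
      stop("interval_days must be >= 0"),
    paternity = if (any(data$sired > data$event_total))
      stop("sired exceeds event_total"),
    weight_change = if (length(unique(data$state)) < 2)
      stop("weight-change model needs both subordinate and guard observations"),
    lrs = {
      if (nrow(data) < 2 || length(unique(data$lrs)) < 2)
        stop("LRS model needs at least two observations with distinct LRS values")
      if (all(data$lrs == 0)) stop("all-zero LRS: count component unidentifiable")
    })
  invisible(data)
}

# assemble the compiled sampler's data list and parameter names
mcmc_frame <- function(spec, data, scaler) {
  re_keys <- c(event = if (spec$model %in% c("transition", "mortality")) "event_from"
                       else "event_id",
               group = "group_id", male = "male_id")
  fam <- switch(spec$model, transition = 3L, mortality = 1L, paternity = 1L,
                weight_change = 2L, lrs = 4L)
  if (spec$model == "transition") {
    d <- data[data$outcome != "dead", , drop = FALSE]
    if (!nrow(d)) stop("no survivor transitions in data")
    X <- design_transition(d, spec$variant, scaler, spec$share_slopes)
    y <- match(d$outcome, LIVE_STATES) - 1
    if (anyNA(y)) stop("transition outcomes must be live states")
    K <- 2L; trials <- NULL; Xz <- NULL
    pnames <- c(paste0("sneaker:", colnames(X)), paste0("guard:", colnames(X)))
  } else if (spec$model == "mortality") {
    d <- data
    if (any(d$interval_days < 0)) stop("interval_days must be >= 0")
    X <- design_mortality(d, spec$variant, scaler, spec$time_interactions)
    y <- as.numeric(d$outcome == "dead")
    K <- 1L; trials <- NULL; Xz <- NULL
    pnames <- colnames(X)
  } else if (spec$model == "paternity") {
    d <- data
    if (any(d$sired > d$event_total)) stop("sired exceeds event_total")
    X <- design_paternity(d, spec$variant, scaler)
    y <- d$sired; trials <- d$event_total
    K <- 1L; Xz <- NULL
    pnames <- colnames(X)
  } else if (spec$model == "weight_change") {
    d <- data
    if (length(unique(d$state)) < 2)
      stop("weight-change model needs both subordinate and guard observations")
    X <- design_weight_change(d)
    y <- d$pct_change
    K <- 1L; trials <- NULL; Xz <- NULL
    pnames <- colnames(X)
  } else { # lrs
    d <- data
    if (nrow(d) < 2 || length(unique(d$lrs)) < 2)
      stop("LRS model needs at least two observations with distinct LRS values")
    if (all(d$lrs == 0)) stop("all-zero LRS: count component unidentifiable")
    X <- design_lrs(d, spec$variant, scaler)
    y <- d$lrs
    K <- 1L; trials <- NULL
    Xz <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
    pnames <- colnames(X)
  }

  res <- spec$random_effects
  re <- matrix(0L, nrow(X), length(res))
  nlev <- integer(length(res))
  re_levels <- list()
  for (i in seq_along(res)) {
    col <- d[[re_keys[[res[i]]]]]
    lv <- unique(col)
    re[, i] <- match(col, lv) - 1L
    nlev[i] <- length(lv)
    re_levels[[res[i]]] <- lv
  }
  pnames <- c(pnames,
              if (!is.null(Xz)) paste0("zero:", colnames(Xz)),
              if (fam == 2L) "sigma", if (fam == 4L) "phi",
              if (length(res)) paste0("sd_", res))
  list(family = fam, X = X, y = as.numeric(y),
       trials = if (!is.null(trials)) as.numeric(trials), Xz = Xz,
       re = re, nlev = nlev, re_levels = re_levels, K = K,
       pnames = pnames, data = d)
}

#' Fit a model by MCMC
#'
#' Runs `spec$chains` independent adaptive Metropolis-within-Gibbs chains
#' (compiled in C++) and returns labelled posterior draws with split R-hat
#' convergence diagnostics and a posterior summary. Draws are seeded from
#' `spec$seed`, one offset per chain, so results are reproducible.
#'
#' @param spec a [model_spec()].
#' @param data the matching design table from [preprocess_cohort()] (the
#'   `transitions` table for transition/mortality fits).
#' @param scaler optional [covariate_scaler]; by default one is fitted from
#'   `data` under the standardization rule (covariates with range outside
#'   \[0, 1\] are z-scored). Pass [scaler_from_params()] output to fit on the
#'   generator's fixed scale.
#' @return An object of class `posterior_draws`: draws array
#'   (iterations x chains x parameters), per-parameter `rhat`, `summary`
#'   data.frame (posterior mean, SD, 95% equal-tailed interval, R-hat), the
#'   spec, the scaler, and reference covariate values/support.
#' @export
fit_mcmc <- function(spec, data, scaler = NULL) {
  if (!inherits(spec, "model_spec")) stop("spec must come from model_spec()")
  validate_fit_data(spec, data)
  covs <- spec_covariates(spec)
  if (is.null(scaler)) scaler <- fit_scaler(data, covs)
  fr <- mcmc_frame(spec, data, scaler)
  ctrl <- list(iterations = spec$iterations, burn_in = spec$burn_in,
               thin = spec$thinning)
  dat <- fr[c("family", "X", "y", "trials", "Xz", "re", "nlev", "K")]
  dat <- dat[!vapply(dat, is.null, logical(1))]
  ch <- vector("list", spec$chains)
  for (c in seq_len(spec$chains)) {
    set.seed(spec$seed + c - 1L)
    ch[[c]] <- mwg_chain(dat, spec$prior, ctrl)$draws
  }
  n_keep <- nrow(ch[[1]])
  draws <- array(NA_real_, c(n_keep, spec$chains, length(fr$pnames)),
                 dimnames = list(NULL, NULL, fr$pnames))
  for (c in seq_len(spec$chains)) draws[, c, ] <- ch[[c]]

  fit <- structure(list(draws = draws, spec = spec, scaler = scaler,
                        n_obs = nrow(fr$X),
                        data_means = covariate_reference(fr$data, covs),
                        support = covariate_support(fr$data, covs)),
                   class = "posterior_draws")
  if (spec$model == "paternity") fit$mean_event_total <- mean(fr$data$event_total)
  fit$rhat <- rhat(fit)
  fit$summary <- summarize_draws(draws, fit$rhat)
  if (any(fit$rhat >= 1.1, na.rm = TRUE))
    warning("R-hat >= 1.1 for: ",
            paste(names(fit$rhat)[fit$rhat >= 1.1], collapse = ", "),
            " -- chains have not converged", call. = FALSE)
  fit
}

covariate_reference <- function(d, covs) {
  out <- vapply(covs, function(cv) mean(d[[cv]]), numeric(1))
  if (!length(covs)) out <- numeric()
  out
}

covariate_support <- function(d, covs) {
  if (!length(covs)) return(list())
  setNames(lapply(covs, function(cv) range(d[[cv]])), covs)
}

summarize_draws <- function(draws, rh) {
  flat <- apply(draws, 3, c)
  data.frame(parameter = dimnames(draws)[[3]],
             mean = colMeans(flat), sd = apply(flat, 2, sd),
             q2.5 = apply(flat, 2, quantile, 0.025),
             q97.5 = apply(flat, 2, quantile, 0.975),
             rhat = unname(rh[dimnames(draws)[[3]]]),
             row.names = NULL)
}

#' Potential scale reduction factor (split R-hat)
#'
#' Split-chain R-hat: each chain is halved, and the between/within variance
#' ratio of the resulting sequences is folded into
#' `sqrt(((n - 1) / n * W + B / n) / W)`. Values near 1 indicate
#' convergence; the package warns at 1.1.
#'
#' @param x a `posterior_draws` object, an iterations x chains matrix, or a
#'   3-d draws array.
#' @return Named vector of R-hat values (scalar for a matrix).
#' @export
rhat <- function(x) {
  if (inherits(x, "posterior_draws")) x <- x$draws
  if (is.matrix(x)) return(split_rhat(x))
  if (length(dim(x)) != 3) stop("x must be a matrix or 3-d array of draws")
  vapply(seq_len(dim(x)[3]), function(j) split_rhat(x[, , j, drop = FALSE][, , 1]),
         numeric(1)) |> setNames(dimnames(x)[[3]])
}

split_rhat <- function(m) {
  if (ncol(m) < 2) stop("R-hat requires at least 2 chains")
  n <- nrow(m)
  if (n < 4) stop("R-hat requires at least 4 retained draws per chain")
  half <- floor(n / 2)
  seqs <- do.call(cbind, lapply(seq_len(ncol(m)), function(c)
    cbind(m[seq_len(half), c], m[(n - half + 1):n, c])))
  nn <- half
  mns <- colMeans(seqs)
  vars <- apply(seqs, 2, var)
  W <- mean(vars)
  B <- nn * var(mns)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size and Monte-Carlo standard error
#'
#' Batch-means estimate: each chain is cut into `sqrt(n)`-sized batches; the
#' MCSE is the standard deviation of batch means over the square root of the
#' number of batches, pooled across chains.
#'
#' @param x `posterior_draws` object or iterations x chains matrix.
#' @param parameter parameter name when `x` is a fit.
#' @return List with `mcse` and `ess` (approximate).
#' @export
mcse <- function(x, parameter = NULL) {
  if (inherits(x, "posterior_draws")) {
    if (is.null(parameter)) stop("parameter required")
    x <- x$draws[, , parameter]
  }
  x <- as.matrix(x)
  n <- nrow(x)
  b <- max(2L, floor(sqrt(n)))
  nb <- floor(n / b)
  bm <- c(apply(x[seq_len(nb * b), , drop = FALSE], 2, function(ch)
    colMeans(matrix(ch, b, nb))))
  se <- sd(bm) / sqrt(length(bm))
  v <- var(c(x))
  list(mcse = se, ess = if (se > 0) v / se^2 else Inf)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", x$spec$model, "model",
      if (x$spec$variant != "none") paste0("(", x$spec$variant, " variant)"), "\n")
  cat("  ", dim(x$draws)[1], "draws x", dim(x$draws)[2], "chains,",
      x$n_obs, "observations\n")
  cat("  max R-hat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @export
summary.posterior_draws <- function(object, ...) object$summary

#' Flattened draws matrix
#'
#' @param fit a `posterior_draws` object.
#' @return Matrix (all retained draws across chains) x parameters.
#' @export
draws_matrix <- function(fit) {
  d <- fit$draws
  matrix(d, dim(d)[1] * dim(d)[2], dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}
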