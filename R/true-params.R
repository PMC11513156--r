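#' Generative parameter set for the synthetic cohort
#'
#' Returns the full parameterization used by [simulate_population()]: the
#' multinomial-logit transition coefficients, state-specific mortality
#' coefficients, crossed random-effect standard deviations, paternity-skew
#' coefficients, per-state oestrus weight-change means, lifetime reproductive
#' success (LRS) coefficients, and the growth-curve parameters. All linear
#' predictors are defined on a fixed, documented covariate scale (see
#' `$scales`), so that fitted coefficients can be compared directly with the
#' generative truth when the same scaler is used at fit time.
#'
#' Defaults describe the study system the package emulates: groups that breed
#' about four times a year; subordinate males that mostly stay subordinate
#' (stay probability about 0.72 conditional on survival) but gain guarding
#' roles as they rise in weight and age rank; a quadratic age effect on
#' guarding peaking at 6.5 years; sneaker roles kept rare (< 0.10
#' probability); between-event mortality near 0.07 with a strongly negative
#' weight slope for guards but none for subordinates; guards losing about
#' 2.36% of body weight per oestrus event while subordinates hold steady; and
#' adult weight plateauing near 1456 g before senescent decline after 8
#' years.
#'
#' @param variant `"quadratic_age"` (default) or `"age_rank"`: which age
#'   covariate the generative transition/mortality laws use. Mirrors the two
#'   fitted model variants.
#' @param ... named overrides replacing any top-level component
#'   (e.g. `mortality = ...`) after defaults are built.
#' @return A list of class `true_params`.
#' @seealso [sim_config()], [simulate_population()]
#' @export
true_params <- function(variant = c("quadratic_age", "age_rank"), ...) {
  variant <- match.arg(variant)

  scales <- list(
    age           = c(centre = 5,    scale = 2.5),
    age_rank      = c(centre = 4,    scale = 3),
    gcw           = c(centre = 0,    scale = 150),
    interval_days = c(centre = 91,   scale = 30),
    weight        = c(centre = 1456, scale = 150)
  )

  if (variant == "quadratic_age") {
    trans_rows <- c("oS", "oK", "oG", "gcw", "age", "age2")
    trans_beta <- cbind(
      sneaker = c(-2.7, -1.4, -1.5, 0.2, 0.30, -0.30),
      guard   = c( 0.2, -0.6,  0.48, 0.7, 0.96, -0.80)
    )
    mort_rows <- c("oS", "oK", "oG", "gcw:oS", "gcw:oK", "gcw:oG",
                   "age", "age2", "interval_days")
    mort_beta <- c(-2.57, -2.5, -2.51, 0, -0.3, -0.55, 0.15, 0, 0.25)
  } else {
    trans_rows <- c("oS", "oK", "oG", "gcw", "age_rank")
    trans_beta <- cbind(
      sneaker = c(-2.7, -1.4, -1.5, 0.2, -0.20),
      guard   = c(-1.35, -0.6, -0.1, 0.7, -0.67)
    )
    mort_rows <- c("oS", "oK", "oG", "gcw:oS", "gcw:oK", "gcw:oG",
                   "age_rank", "interval_days")
    mort_beta <- c(-2.57, -2.5, -2.51, 0, -0.3, -0.55, -0.15, 0.25)
  }
  rownames(trans_beta) <- trans_rows
  mort_beta <- setNames(mort_beta, mort_rows)

  out <- list(
    variant = variant,
    scales = scales,
    transition = list(
      beta = trans_beta,
      sd = c(event = 0.30, group = 0.20, male = 0.30)
    ),
    mortality = list(
      beta = mort_beta,
      sd = c(event = 0.30, group = 0.20, male = 0.30)
    ),
    paternity = list(
      # softmax allocation of each pup across males present at the event
      gcw = 0.5, guard = 2.5, sneaker = 1.5, sd_male = 0.30,
      mean_extra_pups = 2.8,  # event total = 1 + Poisson(mean_extra_pups)
      litter_prob = 0.5       # fraction of events with a pedigree-assigned litter
    ),
    weight_change = list(
      mean = c(subordinate = 0.21, sneaker = -1.0, guard = -2.36),  # percent
      sd = 4.0,
      re_sd = c(event = 0.5, group = 0.3, male = 0.5)
    ),
    lrs = list(
      zero_intercept = -0.34,  # logit of structural-zero probability
      mu_intercept = 1.1,      # log mean of the count component
      gcw = 0.40,              # slope on group-centred weight at first guarding
      age_rank = 0.0,
      phi = 1.2,
      sd_group = 0.30
    ),
    growth = list(
      neonate = 100, adult = 1456, rate = 1.1,
      senescence_onset = 8, decline = 25,
      frailty_sd = 60, measurement_sd = 20
    )
  )

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(out))
    if (length(bad)) stop("unknown true_params components: ", paste(bad, collapse = ", "))
    out[names(dots)] <- dots
  }
  validate_true_params(out)
  structure(out, class = "true_params")
}

validate_true_params <- function(tp) {
  stopifnot(all(is.finite(tp$transition$beta)), all(is.finite(tp$mortality$beta)))
  if (any(tp$transition$sd < 0) || any(tp$mortality$sd < 0))
    stop("random-effect standard deviations must be >= 0")
  if (tp$weight_change$sd <= 0) stop("weight-change residual SD must be > 0")
  if (tp$lrs$phi <= 0) stop("ZINB dispersion must be > 0")
  invisible(tp)
}

#' Fixed covariate scaler implied by a generative parameter set
#'
#' The generator defines its linear predictors on fixed covariate scales
#' (`true_params()$scales`). This helper packages those constants as a
#' [covariate_scaler] so a fit can standardize with the exact generative
#' constants, making fitted coefficients directly comparable to the truth in
#' parameter-recovery studies.
#'
#' @param params a `true_params` object.
#' @return A `covariate_scaler`.
#' @export
scaler_from_params <- function(params) {
  sc <- params$scales
  new_scaler(
    centre = vapply(sc, `[[`, numeric(1), "centre"),
    scale = vapply(sc, `[[`, numeric(1), "scale"),
    method = setNames(rep("zscore", length(sc)), names(sc))
  )
}
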