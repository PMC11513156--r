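# Design-matrix construction shared by the generator, the likelihoods, the
# MCMC fits and posterior prediction. Keeping a single builder guarantees the
# generative and fitted models use byte-identical covariate codings.

ORIGIN_COLS <- c(subordinate = "oS", sneaker = "oK", guard = "oG")

age_terms <- function(variant) {
  if (variant == "age_rank") "age_rank" else c("age", "age2")
}

# standardized covariate columns on the model scale; "age2" is the square of
# standardized age (computed after scaling, the usual orthogonal-free coding)
z_covariates <- function(data, covs, scaler) {
  out <- list()
  for (cv in covs) {
    if (cv == "age2") {
      out[["age2"]] <- scaler_apply(scaler, data[["age"]], "age")^2
    } else {
      out[[cv]] <- scaler_apply(scaler, data[[cv]], cv)
    }
  }
  out
}

#' Build the fixed-effect design matrix for the transition submodel
#'
#' One row per interval, columns: origin-state intercept dummies `oS`, `oK`,
#' `oG`, plus group-centred weight and the variant's age term(s), either
#' shared across origin states or interacted with them.
#'
#' @param data data.frame with `origin_state`, `gcw`, `age`, `age_rank`.
#' @param variant `"age_rank"` or `"quadratic_age"`.
#' @param scaler `covariate_scaler` covering `gcw`, `age`/`age_rank`.
#' @param share_slopes if `FALSE`, covariate slopes are origin-state-specific
#'   (columns like `gcw:oS`).
#' @return Numeric matrix with canonical column names.
#' @keywords internal
#' @export
design_transition <- function(data, variant, scaler, share_slopes = TRUE) {
  covs <- c("gcw", age_terms(variant))
  z <- z_covariates(data, covs, scaler)
  dummies <- sapply(names(ORIGIN_COLS), function(s) as.numeric(data$origin_state == s))
  if (is.null(dim(dummies))) dummies <- matrix(dummies, nrow = nrow(data))
  colnames(dummies) <- ORIGIN_COLS
  if (share_slopes) {
    X <- cbind(dummies, do.call(cbind, z))
    colnames(X) <- c(ORIGIN_COLS, covs)
  } else {
    inter <- lapply(covs, function(cv) {
      m <- dummies * z[[cv]]
      colnames(m) <- paste0(cv, ":", ORIGIN_COLS)
      m
    })
    X <- do.call(cbind, c(list(dummies), inter))
  }
  X
}

#' Build the fixed-effect design matrix for the mortality submodel
#'
#' Columns: origin-state intercepts `oS`, `oK`, `oG`; state-specific
#' group-centred-weight slopes `gcw:oS`, `gcw:oK`, `gcw:oG`; the variant's
#' age term(s) shared across states; and the (standardized) time to the next
#' oestrus event `interval_days`. With `time_interactions = TRUE`,
#' interval-by-covariate interaction columns are appended (off by default;
#' none proved credible in the motivating analysis).
#'
#' @inheritParams design_transition
#' @param time_interactions add `interval_days:` interaction columns.
#' @keywords internal
#' @export
design_mortality <- function(data, variant, scaler, time_interactions = FALSE) {
  at <- age_terms(variant)
  z <- z_covariates(data, c("gcw", at, "interval_days"), scaler)
  dummies <- sapply(names(ORIGIN_COLS), function(s) as.numeric(data$origin_state == s))
  if (is.null(dim(dummies))) dummies <- matrix(dummies, nrow = nrow(data))
  colnames(dummies) <- ORIGIN_COLS
  wcols <- dummies * z$gcw
  colnames(wcols) <- paste0("gcw:", ORIGIN_COLS)
  X <- cbind(dummies, wcols,
             do.call(cbind, setNames(z[at], at)),
             interval_days = z$interval_days)
  if (time_interactions) {
    for (cv in c("gcw", at)) {
      X <- cbind(X, z$interval_days * z[[cv]])
      colnames(X)[ncol(X)] <- paste0("interval_days:", cv)
    }
  }
  X
}

design_paternity <- function(data, variant, scaler) {
  z <- z_covariates(data, c("gcw", age_terms(variant)), scaler)
  X <- cbind(1, do.call(cbind, z))
  colnames(X) <- c("(Intercept)", names(z))
  X
}

design_weight_change <- function(data) {
  X <- cbind(1, as.numeric(data$state == "guard"))
  colnames(X) <- c("(Intercept)", "state_guard")
  X
}

design_lrs <- function(data, variant, scaler) {
  covs <- if (variant == "relative") c("gcw", "age_rank") else c("weight", "age")
  z <- z_covariates(data, covs, scaler)
  X <- cbind(1, do.call(cbind, z))
  colnames(X) <- c("(Intercept)", covs)
  X
}
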