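#' Covariate standardization with a persistable scaler
#'
#' Numerical covariates whose observed range is not contained in \[0, 1\] are
#' centred to mean 0 and scaled to SD 1; covariates already inside \[0, 1\]
#' (e.g. dummy indicators) pass through unchanged. The fitted centre/scale
#' pairs are kept so the identical transform can be re-applied at prediction
#' time and inverted exactly.
#'
#' @param x numeric vector to standardize.
#' @param scaler an existing `covariate_scaler` to reuse, or `NULL` to fit a
#'   new one from `x`.
#' @param name covariate name used to look up / store the transform.
#' @return A list with `values` (transformed vector) and `scaler` (the
#'   `covariate_scaler`, augmented with `name` if it was newly fitted).
#' @examples
#' s <- standardize(c(-200, 0, 200), name = "gcw")
#' round(mean(s$values), 12)  # 0
#' @export
standardize <- function(x, scaler = NULL, name = "x") {
  if (is.null(scaler)) scaler <- new_scaler()
  if (!name %in% names(scaler$centre)) {
    if (length(unique(x)) < 2) stop("cannot fit a scaler for constant covariate '", name, "'")
    rng <- range(x)
    if (rng[1] >= 0 && rng[2] <= 1) {
      scaler <- add_to_scaler(scaler, name, 0, 1, "identity")
    } else {
      s <- sd(x)
      if (s == 0) stop("zero variance in covariate '", name, "'")
      scaler <- add_to_scaler(scaler, name, mean(x), s, "zscore")
    }
  }
  list(values = scaler_apply(scaler, x, name), scaler = scaler)
}

#' Construct a covariate scaler from explicit constants
#'
#' @param centre named numeric vector of centres.
#' @param scale named numeric vector of scales (> 0).
#' @param method named character vector, `"zscore"` or `"identity"`.
#' @return A `covariate_scaler`.
#' @export
new_scaler <- function(centre = numeric(), scale = numeric(), method = character()) {
  if (any(scale <= 0)) stop("scaler scales must be > 0")
  structure(list(centre = centre, scale = scale, method = method),
            class = "covariate_scaler")
}

add_to_scaler <- function(scaler, name, centre, scale, method) {
  scaler$centre[name] <- centre
  scaler$scale[name] <- scale
  scaler$method[name] <- method
  scaler
}

scaler_apply <- function(scaler, x, name) {
  if (!name %in% names(scaler$centre)) stop("scaler has no entry for covariate '", name, "'")
  if (scaler$method[[name]] == "identity") return(x)
  (x - scaler$centre[[name]]) / scaler$scale[[name]]
}

scaler_invert <- function(scaler, z, name) {
  if (!name %in% names(scaler$centre)) stop("scaler has no entry for covariate '", name, "'")
  if (scaler$method[[name]] == "identity") return(z)
  z * scaler$scale[[name]] + scaler$centre[[name]]
}

#' Fit a scaler for several columns of a data frame
#'
#' Applies the \[0, 1\]-range rule of [standardize()] independently to each
#' requested column.
#'
#' @param data data.frame holding the covariates.
#' @param covariates character vector of column names.
#' @return A `covariate_scaler` covering all requested columns.
#' @export
fit_scaler <- function(data, covariates) {
  scaler <- new_scaler()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stop("covariate '", cv, "' not found in data")
    if (length(unique(x)) < 2) stop("cannot fit a scaler for constant covariate '", cv, "'")
    rng <- range(x)
    if (rng[1] >= 0 && rng[2] <= 1) {
      scaler <- add_to_scaler(scaler, cv, 0, 1, "identity")
    } else {
      scaler <- add_to_scaler(scaler, cv, mean(x), sd(x), "zscore")
    }
  }
  scaler
}

#' @export
print.covariate_scaler <- function(x, ...) {
  cat("covariate_scaler:\n")
  if (!length(x$centre)) { cat("  (empty)\n"); return(invisible(x)) }
  df <- data.frame(covariate = names(x$centre), centre = unname(x$centre),
                   scale = unname(x$scale), method = unname(x$method))
  print(df, row.names = FALSE)
  invisible(x)
}

scaler_to_json <- function(scaler, path) {
  jsonlite::write_json(list(centre = as.list(scaler$centre),
                            scale = as.list(scaler$scale),
                            method = as.list(scaler$method)),
                       path, auto_unbox = TRUE, digits = NA)
}

scaler_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_scaler(unlist(x$centre), unlist(x$scale), unlist(x$method))
}
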