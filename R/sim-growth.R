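#' Expected body weight at a given age
#'
#' Monotone saturating (von Bertalanffy-shaped) growth to an adult plateau,
#' frozen at the senescence onset age, followed by a strictly linear decline.
#' The field system shows growth to roughly 1.4-1.5 kg and weight loss beyond
#' about 8 years; the exact curve is a documented stand-in, not an estimate.
#'
#' `base(a) = neonate + (adult - neonate) * (1 - exp(-rate * a))`;
#' `weight(a) = base(min(a, onset)) - decline * max(0, a - onset)`.
#'
#' @param age age in years (vectorized, must be >= 0).
#' @param params growth parameter list with elements `neonate`, `adult`,
#'   `rate`, `senescence_onset`, `decline` (see [true_params()]`$growth`).
#' @param frailty additive individual deviation of the adult plateau in
#'   grams (default 0), recycled along `age`.
#' @return Expected weight in grams.
#' @examples
#' growth_curve(0, true_params()$growth)   # neonate weight
#' growth_curve(8, true_params()$growth)   # near the adult plateau
#' @export
growth_curve <- function(age, params, frailty = 0) {
  if (any(age < 0)) stop("age must be >= 0")
  a0 <- pmin(age, params$senescence_onset)
  w <- params$neonate + (params$adult + frailty - params$neonate) *
    (1 - exp(-params$rate * a0))
  w - params$decline * pmax(0, age - params$senescence_onset)
}
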