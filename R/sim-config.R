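#' Configuration for the synthetic cohort generator
#'
#' Describes the demographic world that [simulate_population()] draws from:
#' number of groups, observation span, adult male group size, oestrus event
#' frequency, and the generative parameter set. Defaults mirror the study
#' system: groups breeding about four times per year, adult (>= 1 year) males
#' entering every oestrus event of their group, and group sizes in the
#' 10-30-adult range typical of banded mongooses.
#'
#' @param n_groups number of social groups (>= 1).
#' @param years observation span in years (> 0).
#' @param mean_adult_males_per_group target mean number of adult males per
#'   group (> 0); recruitment is calibrated to hold group size near this.
#' @param events_per_year mean number of oestrus events per group per year.
#' @param event_jitter log-scale SD of inter-event gaps (0 = regular
#'   schedule).
#' @param adult_age age (years) at which males start attending oestrus events
#'   (sexual maturity, default 1).
#' @param seed integer seed; a fixed seed makes the exported dataset bundle
#'   byte-identical across runs.
#' @param true_params generative parameter set, see [true_params()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 20, years = 12, mean_adult_males_per_group = 8,
                       events_per_year = 4, event_jitter = 0.2, adult_age = 1,
                       seed = 1L, true_params = socialstate::true_params()) {
  if (!is.numeric(n_groups) || n_groups < 1) stop("n_groups must be >= 1")
  if (!is.numeric(years) || years <= 0) stop("years must be > 0")
  if (!is.numeric(mean_adult_males_per_group) || mean_adult_males_per_group <= 0)
    stop("mean_adult_males_per_group must be > 0")
  if (!is.numeric(events_per_year) || events_per_year <= 0)
    stop("events_per_year must be > 0")
  if (event_jitter < 0) stop("event_jitter must be >= 0")
  if (!inherits(true_params, "true_params")) stop("true_params must come from true_params()")
  structure(list(
    n_groups = as.integer(n_groups), years = years,
    mean_adult_males_per_group = mean_adult_males_per_group,
    events_per_year = events_per_year, event_jitter = event_jitter,
    adult_age = adult_age, seed = as.integer(seed), true_params = true_params
  ), class = "sim_config")
}
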