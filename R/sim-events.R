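#' Schedule oestrus events for one group
#'
#' Draws an ordered, non-overlapping sequence of oestrus events over a group
#' observation window. Start-to-start gaps are `mean_gap * exp(e)` with
#' `e ~ N(0, jitter)`, so `jitter = 0` gives a perfectly regular schedule at
#' `1 / events_per_year` years; the first event starts half a mean gap into
#' the window. Each event lasts 7-10 days (the span of synchronized female
#' oestrus within a group).
#'
#' @param years length of the observation window in years (> 0).
#' @param events_per_year mean number of events per year.
#' @param jitter log-scale SD of the start-to-start gaps (>= 0).
#' @param origin calendar offset in days added to all dates (default 0).
#' @return A data.frame with columns `start_day` and `end_day` (days from the
#'   window origin), chronologically ordered.
#' @examples
#' set.seed(1)
#' schedule_events(1, 4, jitter = 0)  # four events about 91.3 days apart
#' @export
schedule_events <- function(years, events_per_year, jitter = 0.2, origin = 0) {
  if (years <= 0) stop("years must be > 0")
  if (events_per_year <= 0) stop("events_per_year must be > 0")
  mean_gap <- 365.25 / events_per_year
  horizon <- years * 365.25
  # draw enough gaps to cover the window, then truncate
  n_max <- max(8L, ceiling(years * events_per_year * 2.5) + 8L)
  gaps <- pmax(mean_gap * exp(rnorm(n_max, 0, jitter)), 12)  # floor keeps events non-overlapping
  starts <- mean_gap / 2 * exp(rnorm(1, 0, jitter)) + cumsum(c(0, gaps))
  durations <- runif(length(starts), 7, 10)
  keep <- (starts + durations) <= horizon
  starts <- starts[keep]
  durations <- durations[keep]
  data.frame(start_day = origin + starts, end_day = origin + starts + durations)
}
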