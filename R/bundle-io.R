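# Canonical dataset bundle on disk: males.csv, events.csv, states.csv,
# paternity.csv, weights.csv, true_params.json. Dates are ISO 8601 (internal
# numeric days are offsets from 2000-01-01); states are integer-coded
# (0 subordinate, 1 sneaker, 2 guard, 3 dead).

DAY_ORIGIN <- as.Date("2000-01-01")

day_to_iso <- function(day) format(DAY_ORIGIN + round(day), "%Y-%m-%d")
iso_to_day <- function(iso) as.numeric(as.Date(iso) - DAY_ORIGIN)

#' Write / read a cohort dataset bundle as CSV + JSON
#'
#' `write_bundle()` exports the five CSV tables plus `true_params.json`;
#' `read_bundle()` reconstructs the in-memory bundle. A fixed simulation seed
#' yields byte-identical files. Fractional days are rounded to whole calendar
#' days on export, the resolution of the field data.
#'
#' @param bundle a `cohort_bundle` from [simulate_population()].
#' @param dir output directory (created if missing).
#' @return `write_bundle()` returns the vector of file paths invisibly;
#'   `read_bundle()` returns a `cohort_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  males <- bundle$males
  males$birth_date <- day_to_iso(males$birth_day)
  males$death_date <- ifelse(is.na(males$death_day), "", day_to_iso(males$death_day))
  events <- bundle$events
  events$start_date <- day_to_iso(events$start_day)
  events$end_date <- day_to_iso(events$end_day)
  states <- bundle$states
  states$state <- state_code(states$state)
  weights <- bundle$weights
  weights$date <- day_to_iso(weights$date_day)
  weights$grams <- round(weights$grams, 1)

  paths <- file.path(dir, c("males.csv", "events.csv", "states.csv",
                            "paternity.csv", "weights.csv", "true_params.json"))
  write.csv(males[, c("male_id", "group_id", "birth_date", "death_date")],
            paths[1], row.names = FALSE)
  write.csv(events[, c("event_id", "group_id", "start_date", "end_date")],
            paths[2], row.names = FALSE)
  write.csv(states[, c("male_id", "group_id", "event_id", "state")],
            paths[3], row.names = FALSE)
  write.csv(bundle$paternity, paths[4], row.names = FALSE)
  write.csv(weights[, c("male_id", "date", "grams")], paths[5], row.names = FALSE)
  true_params_to_json(bundle$true_params, paths[6])
  invisible(paths)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  males <- read.csv(file.path(dir, "males.csv"), colClasses = "character")
  males$birth_day <- iso_to_day(males$birth_date)
  males$death_day <- ifelse(males$death_date == "", NA_real_, iso_to_day(males$death_date))
  events <- read.csv(file.path(dir, "events.csv"), colClasses = "character")
  events$start_day <- iso_to_day(events$start_date)
  events$end_day <- iso_to_day(events$end_date)
  states <- read.csv(file.path(dir, "states.csv"))
  states$state <- state_label(states$state)
  weights <- read.csv(file.path(dir, "weights.csv"))
  weights$date_day <- iso_to_day(weights$date)
  tp_path <- file.path(dir, "true_params.json")
  tp <- if (file.exists(tp_path)) true_params_from_json(tp_path) else NULL
  structure(list(
    males = males[, c("male_id", "group_id", "birth_day", "death_day")],
    events = events[, c("event_id", "group_id", "start_day", "end_day")],
    states = states[, c("male_id", "group_id", "event_id", "state")],
    paternity = read.csv(file.path(dir, "paternity.csv")),
    weights = weights[, c("male_id", "date_day", "grams")],
    true_params = tp, config = NULL), class = "cohort_bundle")
}

true_params_to_json <- function(tp, path) {
  x <- unclass(tp)
  x$transition$beta <- mat_to_list(tp$transition$beta)
  x$mortality$beta <- as.list(tp$mortality$beta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}

true_params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- sapply(x$transition$beta, unlist)
  x$transition$beta <- tb
  x$transition$sd <- unlist(x$transition$sd)
  x$mortality$beta <- unlist(x$mortality$beta)
  x$mortality$sd <- unlist(x$mortality$sd)
  x$weight_change$mean <- unlist(x$weight_change$mean)
  x$weight_change$re_sd <- unlist(x$weight_change$re_sd)
  x$scales <- lapply(x$scales, unlist)
  structure(x, class = "true_params")
}

mat_to_list <- function(m) {
  out <- lapply(seq_len(ncol(m)), function(j) as.list(setNames(m[, j], rownames(m))))
  names(out) <- colnames(m)
  out
}
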