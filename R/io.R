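#' Read the three standard study inputs
#'
#' CSV readers for the shapes emitted by passive-sensing research apps and by
#' [simulate_study()]: an event log (`participant_id`, `timestamp`, `state`),
#' a survey log (`participant_id`, `timestamp`, `instrument`, `score`) and a
#' participant roster (`participant_id`, `group`, `age`, `gender`, optional
#' `bacs_*` columns). Timestamps are parsed as ISO-8601 in the study
#' timezone.
#'
#' @param path CSV file path.
#' @param tz Study timezone.
#' @return A tibble.
#' @export
read_events <- function(path, tz = "UTC") {
  if (!file.exists(path)) rlang::abort(sprintf("events file not found: %s", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    state = readr::col_character()))
  d$timestamp <- lubridate::ymd_hms(d$timestamp, tz = tz, quiet = TRUE)
  d
}

#' @rdname read_events
#' @export
read_surveys <- function(path, tz = "UTC") {
  if (!file.exists(path)) rlang::abort(sprintf("surveys file not found: %s", path))
  d <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    instrument = readr::col_character(),
    score = readr::col_double()))
  d$timestamp <- lubridate::ymd_hms(d$timestamp, tz = tz, quiet = TRUE)
  d
}

#' @rdname read_events
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("roster file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    gender = readr::col_character(),
    age = readr::col_integer(),
    .default = readr::col_double()))
}
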