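#' Aggregate survey and cognition responses to participant-day resolution
#'
#' Scores are averaged within each participant-day-instrument cell: when more
#' than one response to the same instrument arrives on one calendar day, the
#' day's value is their arithmetic mean (e.g. PHQ-9 totals of 10 and 11 on
#' the same day become 10.5). Days with no response carry `NA`, never zero.
#' The calendar date of a response is taken in the study timezone, the same
#' clock the screen metrics use, so independent and dependent variables share
#' one day grid.
#'
#' Responses with a score outside the instrument's documented range
#' (mood/PHQ-9 0-27, anxiety/GAD-7 0-21, sleep and social 0-10; cognition is
#' unbounded) or an unknown instrument are rejected and logged.
#'
#' @param responses Data frame with columns `participant_id`, `timestamp`
#'   (POSIXct or ISO-8601 character), `instrument`, `score`.
#' @param tz Study timezone used to assign calendar dates.
#' @param quiet Suppress the rejection-log message.
#' @return A tibble with one row per participant-day having any response:
#'   `participant_id`, `date`, and one column per instrument (`mood`,
#'   `anxiety`, `sleep`, `social`, `cognition`), `NA` where that instrument
#'   was not answered that day. Rejection counts are attached as attribute
#'   `"log"`.
#' @export
#' @examples
#' rs <- tibble::tibble(
#'   participant_id = "P001",
#'   timestamp = as.POSIXct("2023-01-02 10:00:00", tz = "UTC") + c(0, 3600),
#'   instrument = "mood", score = c(10, 11)
#' )
#' aggregate_daily(rs)$mood  # 10.5
aggregate_daily <- function(responses, tz = "UTC", quiet = FALSE) {
  stopifnot(all(c("participant_id", "timestamp", "instrument", "score") %in%
                  names(responses)))
  responses <- tibble::as_tibble(responses)
  if (!inherits(responses$timestamp, "POSIXct")) {
    responses$timestamp <- suppressWarnings(
      lubridate::ymd_hms(as.character(responses$timestamp), tz = tz,
                         quiet = TRUE))
  }
  rng <- instrument_ranges()
  checked <- responses |>
    dplyr::left_join(rng, by = "instrument") |>
    dplyr::mutate(
      bad_instrument = is.na(.data$lower),
      out_of_range = !.data$bad_instrument &
        (!is.finite(.data$score) | .data$score < .data$lower |
           .data$score > .data$upper),
      bad_time = is.na(.data$timestamp)
    )
  n_bad_instrument <- sum(checked$bad_instrument)
  n_out_of_range <- sum(checked$out_of_range)
  n_bad_time <- sum(checked$bad_time, na.rm = TRUE)
  keep <- !(checked$bad_instrument | checked$out_of_range | checked$bad_time)

  daily <- checked[keep, ] |>
    dplyr::mutate(date = lubridate::as_date(
      lubridate::with_tz(.data$timestamp, tz))) |>
    dplyr::group_by(.data$participant_id, .data$date, .data$instrument) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "instrument", values_from = "score")

  for (ins in rng$instrument) {
    if (!ins %in% names(daily)) daily[[ins]] <- NA_real_
  }
  daily <- daily |>
    dplyr::select("participant_id", "date", dplyr::all_of(rng$instrument)) |>
    dplyr::arrange(.data$participant_id, .data$date)

  if (!quiet && (n_bad_instrument + n_out_of_range + n_bad_time) > 0) {
    rlang::inform(sprintf(
      "aggregate_daily: rejected %d out-of-range score(s), %d unknown instrument(s), %d unparseable timestamp(s)",
      n_out_of_range, n_bad_instrument, n_bad_time))
  }
  attr(daily, "log") <- list(n_out_of_range = n_out_of_range,
                             n_bad_instrument = n_bad_instrument,
                             n_bad_time = n_bad_time)
  daily
}
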