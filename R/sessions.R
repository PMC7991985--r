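#' Convert screen on/off event logs into usage sessions
#'
#' Pairs each "Screen On" event with the next "Screen Off" event for the same
#' participant to form one usage session. Events are sorted by participant and
#' timestamp first. Malformed subsequences follow a drop-and-log repair
#' policy: an On with no following Off before the next On (or before the end
#' of the stream) is dropped, as is an Off with no pending On — a duration
#' cannot be attributed to either without inventing data. Records with an
#' unparseable timestamp or unknown state are rejected and logged, and
#' processing continues.
#'
#' A session shorter than 15 seconds (strictly) is flagged as a habitual
#' "check", the conventional proxy for phone preoccupation.
#'
#' @param events Data frame with columns `participant_id`, `timestamp`
#'   (POSIXct, or character parseable as ISO-8601), and `state`
#'   ("Screen On"/"Screen Off", "On"/"Off" also accepted, case-insensitive).
#' @param tz Study timezone used when timestamps arrive as character.
#' @param quiet Suppress the repair-log message.
#' @return A tibble with columns `participant_id`, `start`, `end`,
#'   `duration_s`, `is_check`, ordered by participant and start time. The
#'   repair log (counts of rejected records and dropped On/Off events) is
#'   attached as attribute `"log"`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   participant_id = "P001",
#'   timestamp = as.POSIXct("2023-01-02 09:00:00", tz = "UTC") + c(0, 30),
#'   state = c("Screen On", "Screen Off")
#' )
#' sessionize(ev)
sessionize <- function(events, tz = "UTC", quiet = FALSE) {
  stopifnot(all(c("participant_id", "timestamp", "state") %in% names(events)))
  events <- tibble::as_tibble(events)

  if (!inherits(events$timestamp, "POSIXct")) {
    parsed <- suppressWarnings(
      lubridate::ymd_hms(as.character(events$timestamp), tz = tz, quiet = TRUE)
    )
  } else {
    parsed <- events$timestamp
  }
  state <- normalize_state(events$state)

  bad <- is.na(parsed) | is.na(state)
  n_rejected <- sum(bad)
  ev <- tibble::tibble(
    participant_id = events$participant_id[!bad],
    timestamp = parsed[!bad],
    state = state[!bad]
  )
  ev <- dplyr::arrange(ev, .data$participant_id, .data$timestamp)

  # within a participant, a session is an On immediately followed by an Off;
  # any other On (followed by On, or last of the stream) dangles and is
  # dropped, any other Off (no pending On) is dropped
  same_pid <- function(i, j) ev$participant_id[i] == ev$participant_id[j]
  n <- nrow(ev)
  if (n == 0) {
    out <- tibble::tibble(
      participant_id = character(), start = as.POSIXct(character(), tz = tz),
      end = as.POSIXct(character(), tz = tz), duration_s = numeric(),
      is_check = logical()
    )
    attr(out, "log") <- list(n_rejected = n_rejected, n_dropped_on = 0L,
                             n_dropped_off = 0L)
    return(out)
  }
  nxt_same <- c(ev$participant_id[-n] == ev$participant_id[-1], FALSE)
  starts <- which(ev$state == "On" & nxt_same &
                    c(ev$state[-1] == "Off", FALSE))
  n_pairs <- length(starts)
  n_dropped_on <- sum(ev$state == "On") - n_pairs
  n_dropped_off <- sum(ev$state == "Off") - n_pairs

  out <- tibble::tibble(
    participant_id = ev$participant_id[starts],
    start = ev$timestamp[starts],
    end = ev$timestamp[starts + 1L],
    duration_s = as.numeric(difftime(ev$timestamp[starts + 1L],
                                     ev$timestamp[starts], units = "secs"))
  )
  out$is_check <- out$duration_s < 15
  log <- list(n_rejected = n_rejected, n_dropped_on = n_dropped_on,
              n_dropped_off = n_dropped_off)
  if (!quiet && (n_rejected > 0 || n_dropped_on > 0 || n_dropped_off > 0)) {
    rlang::inform(sprintf(
      "sessionize: rejected %d record(s), dropped %d unmatched On and %d unmatched Off event(s)",
      n_rejected, n_dropped_on, n_dropped_off))
  }
  attr(out, "log") <- log
  out
}

normalize_state <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("screen on", "on")] <- "On"
  out[x %in% c("screen off", "off")] <- "Off"
  out
}

#' Aggregate usage sessions into per participant-day screen metrics
#'
#' Computes, for every participant-day with any usage, the four screen
#' metrics used throughout the analyses: raw screen time (seconds, the sum of
#' session durations), number of sessions, session time (screen time divided
#' by the number of sessions, i.e. the day's mean session duration), and the
#' number of checks (sessions under 15 seconds).
#'
#' Sessions that cross local midnight are split at the day boundary; each
#' fragment contributes to its own day and its check status is re-evaluated
#' from the fragment duration, so daily screen time is conserved exactly.
#' Days with no usage emit no row (missing, never zero).
#'
#' @param sessions Output of [sessionize()] (columns `participant_id`,
#'   `start`, `end`, `duration_s`).
#' @param tz Study timezone defining the day boundary (local midnight).
#' @return A tibble with columns `participant_id`, `date`, `screen_time_s`,
#'   `n_sessions`, `session_time_s`, `n_checks`.
#' @export
daily_metrics <- function(sessions, tz = "UTC") {
  stopifnot(all(c("participant_id", "start", "end", "duration_s") %in%
                  names(sessions)))
  frag <- split_at_midnight(sessions, tz = tz)
  frag |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      screen_time_s = sum(.data$duration_s),
      n_sessions = dplyr::n(),
      n_checks = sum(.data$duration_s < 15),
      .groups = "drop"
    ) |>
    dplyr::mutate(session_time_s = .data$screen_time_s / .data$n_sessions) |>
    dplyr::select("participant_id", "date", "screen_time_s", "n_sessions",
                  "session_time_s", "n_checks") |>
    dplyr::arrange(.data$participant_id, .data$date)
}

# split sessions at local midnight; returns fragments with participant_id,
# date, duration_s. Zero-length fragments created by a cut exactly at a
# boundary are dropped; genuine zero-duration sessions (On and Off at the
# same instant) are kept and count as checks.
split_at_midnight <- function(sessions, tz = "UTC") {
  if (nrow(sessions) == 0) {
    return(tibble::tibble(participant_id = character(),
                          date = as.Date(character()), duration_s = numeric()))
  }
  d_start <- lubridate::as_date(lubridate::with_tz(sessions$start, tz))
  d_end <- lubridate::as_date(lubridate::with_tz(sessions$end, tz))
  simple <- d_start == d_end
  out <- tibble::tibble(
    participant_id = sessions$participant_id[simple],
    date = d_start[simple],
    duration_s = sessions$duration_s[simple]
  )
  if (all(simple)) return(out)

  span <- sessions[!simple, , drop = FALSE]
  pieces <- purrr::pmap(
    list(span$participant_id, as.numeric(span$start), as.numeric(span$end),
         as.list(seq_len(nrow(span)))),
    function(pid, s, e, i) {
      # wall-clock midnights strictly inside (s, e)
      days <- seq(d_start[!simple][i], d_end[!simple][i], by = "day")
      cuts <- as.numeric(lubridate::force_tz(
        lubridate::as_datetime(days[-1]), tzone = tz))
      bounds <- c(s, cuts, e)
      dur <- diff(bounds)
      keep <- dur > 0
      tibble::tibble(participant_id = pid, date = days[keep],
                     duration_s = dur[keep])
    }
  )
  dplyr::bind_rows(out, dplyr::bind_rows(pieces))
}
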