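#' Length of the longest run of consecutive calendar dates
#'
#' @param dates A vector of `Date`s (duplicates and unsorted input allowed).
#' @return Integer length of the longest run of consecutive days; 0 for an
#'   empty input.
#' @export
#' @examples
#' longest_consecutive_run(as.Date("2023-01-01") + c(0, 1, 2, 5, 6))  # 3
longest_consecutive_run <- function(dates) {
  d <- sort(unique(dates))
  if (length(d) == 0) return(0L)
  gaps <- c(TRUE, diff(as.integer(d)) != 1L)
  max(table(cumsum(gaps)))
}

#' Apply the study inclusion filters
#'
#' A participant is included iff (a) they answered at least one self-reported
#' survey (mood, anxiety, sleep or social — cognition tests do not count) and
#' (b) their daily screen metrics contain at least `min_consecutive_days`
#' consecutive calendar days each with at least one session (the passive-data
#' cutoff). The exclusion report names each removed participant and the
#' criterion(s) failed; together with the included roster it partitions the
#' input roster exactly.
#'
#' @param roster Participant roster (column `participant_id` at minimum).
#' @param daily_metrics Output of [daily_metrics()].
#' @param daily_symptoms Output of [aggregate_daily()].
#' @param min_consecutive_days Passive-data cutoff (default 5 consecutive
#'   days of usage).
#' @param require_survey Require at least one non-cognition survey response.
#' @return A list with `included` (roster rows passing both filters) and
#'   `exclusions` (tibble `participant_id`, `reason`).
#' @export
filter_cohort <- function(roster, daily_metrics, daily_symptoms,
                          min_consecutive_days = 5, require_survey = TRUE) {
  stopifnot("participant_id" %in% names(roster))
  orphan <- setdiff(unique(daily_metrics$participant_id),
                    roster$participant_id)
  if (length(orphan) > 0) {
    rlang::abort(sprintf(
      "daily metrics contain participant(s) absent from the roster: %s",
      paste(orphan, collapse = ", ")))
  }

  runs <- daily_metrics |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(max_run = longest_consecutive_run(.data$date),
                     .groups = "drop")

  sym <- symptom_instruments()
  has_survey <- daily_symptoms |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      any_survey = any(!is.na(unlist(dplyr::pick(dplyr::all_of(sym))))),
      .groups = "drop")

  status <- roster |>
    dplyr::left_join(runs, by = "participant_id") |>
    dplyr::left_join(has_survey, by = "participant_id") |>
    dplyr::mutate(
      max_run = dplyr::coalesce(.data$max_run, 0L),
      any_survey = dplyr::coalesce(.data$any_survey, FALSE),
      fail_usage = .data$max_run < min_consecutive_days,
      fail_survey = require_survey & !.data$any_survey
    )

  reasons <- purrr::map2_chr(status$fail_survey, status$fail_usage,
    function(fs, fu) {
      paste(c(if (fs) "no_self_reported_survey",
              if (fu) sprintf("fewer_than_%d_consecutive_usage_days",
                              min_consecutive_days)),
            collapse = ";")
    })
  excluded <- status$fail_usage | status$fail_survey

  list(
    included = roster[!excluded, , drop = FALSE],
    exclusions = tibble::tibble(
      participant_id = status$participant_id[excluded],
      reason = reasons[excluded]
    )
  )
}

#' Assemble the per participant-day analysis table
#'
#' Joins daily screen metrics, daily symptom scores and roster attributes on
#' (participant, date), restricted to days with any usage (the metrics table
#' is the spine). Symptom columns are `NA` where no survey was answered that
#' day; roster attributes (group, age bracket, gender) broadcast to all of a
#' participant's rows. The age bracket splits at 30 years (`under30` is
#' strictly below 30).
#'
#' @param included Roster of included participants (from [filter_cohort()]),
#'   with columns `participant_id`, `group`, `age`, `gender`.
#' @param daily_metrics Output of [daily_metrics()].
#' @param daily_symptoms Output of [aggregate_daily()].
#' @return A tibble keyed by (`participant_id`, `date`) with the four screen
#'   metrics, the five symptom scores, `group`, `age_bracket`, `gender`.
#' @export
build_analysis_table <- function(included, daily_metrics, daily_symptoms) {
  stopifnot(all(c("participant_id", "group", "age", "gender") %in%
                  names(included)))
  spine <- daily_metrics |>
    dplyr::semi_join(included, by = "participant_id")
  spine |>
    dplyr::left_join(daily_symptoms, by = c("participant_id", "date")) |>
    dplyr::left_join(
      included |>
        dplyr::mutate(age_bracket = ifelse(.data$age < 30, "under30",
                                           "over30")) |>
        dplyr::select("participant_id", "group", "age_bracket", "gender"),
      by = "participant_id") |>
    dplyr::arrange(.data$participant_id, .data$date)
}
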