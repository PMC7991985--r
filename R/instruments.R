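#' Survey instrument definitions
#'
#' The five instruments carried by the survey stream: PHQ-9 mood (0-27),
#' GAD-7 anxiety (0-21), sleep and sociability on a 0-10 scale, and a
#' smartphone cognition score (a Trails-B-style task summary, unbounded).
#' `midpoint` is the centre of the score range used by the synthetic
#' generator; `scale_sd` is the generator's raw-score standard deviation per
#' standardized unit.
#'
#' @return A tibble with columns `instrument`, `lower`, `upper`, `midpoint`,
#'   `scale_sd`. `lower`/`upper` are `-Inf`/`Inf` for cognition.
#' @export
#' @examples
#' instrument_ranges()
instrument_ranges <- function() {
  tibble::tibble(
    instrument = c("mood", "anxiety", "sleep", "social", "cognition"),
    lower      = c(0, 0, 0, 0, -Inf),
    upper      = c(27, 21, 10, 10, Inf),
    midpoint   = c(13.5, 10.5, 5, 5, 50),
    scale_sd   = c(4, 3, 2, 2, 10)
  )
}

#' @rdname instrument_ranges
#' @export
symptom_instruments <- function() c("mood", "anxiety", "sleep", "social")

# internal: the four daily screen metrics and their analysis-table columns
metric_columns <- function() {
  c(
    screen_time  = "screen_time_s",
    session_time = "session_time_s",
    n_checks     = "n_checks",
    n_sessions   = "n_sessions"
  )
}
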