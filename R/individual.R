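#' Participants eligible for individual-level regression
#'
#' Only participants with at least one daily score in every one of the four
#' self-report categories (mood, anxiety, sleep, social) enter the
#' individual-level analysis; partial responders are excluded.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @return Character vector of eligible participant ids.
#' @export
eligible_participants <- function(analysis_table) {
  sym <- symptom_instruments()
  analysis_table |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sym), ~ any(!is.na(.x))),
                     .groups = "drop") |>
    dplyr::filter(dplyr::if_all(dplyr::all_of(sym), identity)) |>
    dplyr::pull("participant_id")
}

#' Per-participant regressions of daily symptoms on daily screen time
#'
#' Fits, for every eligible participant and each of the four symptom
#' instruments, an ordinary least-squares regression of the raw daily
#' symptom score on that day's screen time. Screen time enters in hours
#' (seconds / 3600) so slopes read as score points per hour; scores are not
#' standardized, exposing the raw between-person heterogeneity of effects.
#' Pairs with fewer than `min_days` paired days are omitted and logged (a
#' slope and intercept need at least 3 points for any residual degree of
#' freedom). Estimates are sorted descending within diagnostic group.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @param eligible Ids from [eligible_participants()]; computed when `NULL`.
#' @param x_metric Screen metric used as the independent variable (default
#'   total daily screen time; any of `names(metric_columns())`).
#' @param min_days Minimum paired days per fit (default 3).
#' @param quiet Suppress the omission-log message.
#' @return A tibble `participant_id`, `group`, `instrument`, `estimate`
#'   (score points per hour), `se`, `n_days`, sorted by group and descending
#'   estimate. Omitted pairs are attached as attribute `"omitted"`.
#' @export
fit_individuals <- function(analysis_table, eligible = NULL,
                            x_metric = "screen_time", min_days = 3,
                            quiet = FALSE) {
  mets <- metric_columns()
  stopifnot(x_metric %in% names(mets))
  if (is.null(eligible)) eligible <- eligible_participants(analysis_table)
  xcol <- mets[[x_metric]]
  sym <- symptom_instruments()

  long <- analysis_table |>
    dplyr::filter(.data$participant_id %in% eligible) |>
    dplyr::select(dplyr::all_of(c("participant_id", "group", xcol, sym))) |>
    tidyr::pivot_longer(dplyr::all_of(sym), names_to = "instrument",
                        values_to = "score") |>
    dplyr::filter(!is.na(.data$score), !is.na(.data[[xcol]]))

  fits <- long |>
    dplyr::group_by(.data$participant_id, .data$group, .data$instrument) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < min_days) {
        return(tibble::tibble(estimate = NA_real_, se = NA_real_, n_days = n,
                              omitted = TRUE, reason = "too_few_paired_days"))
      }
      x_hours <- d[[xcol]] / 3600
      if (sd(x_hours) == 0) {
        return(tibble::tibble(estimate = NA_real_, se = NA_real_, n_days = n,
                              omitted = TRUE, reason = "constant_screen_time"))
      }
      fit <- lm(d$score ~ x_hours)
      cf <- summary(fit)$coefficients
      tibble::tibble(estimate = unname(cf["x_hours", 1]),
                     se = unname(cf["x_hours", 2]), n_days = n,
                     omitted = FALSE, reason = NA_character_)
    }) |>
    dplyr::ungroup()

  omitted <- fits |>
    dplyr::filter(.data$omitted) |>
    dplyr::select("participant_id", "group", "instrument", "n_days", "reason")
  out <- fits |>
    dplyr::filter(!.data$omitted) |>
    dplyr::select("participant_id", "group", "instrument", "estimate", "se",
                  "n_days") |>
    dplyr::arrange(.data$group, dplyr::desc(.data$estimate))
  if (!quiet && nrow(omitted) > 0) {
    rlang::inform(sprintf(
      "fit_individuals: omitted %d participant-instrument pair(s) (%s)",
      nrow(omitted),
      paste(unique(omitted$reason), collapse = ", ")))
  }
  attr(out, "omitted") <- omitted
  out
}

#' Group-level digest of individual estimates
#'
#' @param estimates Output of [fit_individuals()].
#' @return A tibble per diagnostic group: `n_estimates`, `n_participants`,
#'   `mean`, `sd`, `min`, `max` over all estimates in the group.
#' @export
summarize_individuals <- function(estimates) {
  estimates |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_estimates = dplyr::n(),
      n_participants = dplyr::n_distinct(.data$participant_id),
      mean = mean(.data$estimate),
      sd = sd(.data$estimate),
      min = min(.data$estimate),
      max = max(.data$estimate),
      .groups = "drop"
    )
}

#' Dot plot of sorted individual estimates
#'
#' One panel per diagnostic group, estimates sorted ascending, in the style
#' of forest-type displays of idiographic effects.
#'
#' @param estimates Output of [fit_individuals()].
#' @return A ggplot object.
#' @export
plot_individuals <- function(estimates) {
  if (nrow(estimates) == 0) rlang::abort("no individual estimates to plot")
  d <- estimates |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$estimate, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$estimate,
                                  colour = .data$instrument)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~ group, scales = "free_x") +
    ggplot2::labs(x = "participant-instrument fit (sorted)",
                  y = "estimate (score points per hour of screen time)") +
    ggplot2::theme_minimal()
}
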