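#' Baseline screening: first-month screen metrics vs baseline cognition
#'
#' For participants with schizophrenia carrying baseline BACS scores,
#' summarizes each of the four screen metrics as the mean of its daily values
#' over the participant's first `first_month_days` study days (counted from
#' their first recorded usage day) and correlates each metric with each of
#' the six BACS subdomains by Spearman rank correlation (average ranks for
#' ties). P values are adjusted by the Benjamini-Hochberg false-discovery-rate
#' procedure, jointly across all 24 metric-subdomain tests by default.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @param roster Roster carrying the `bacs_*` columns (see
#'   [bacs_subdomains()]).
#' @param first_month_days Window length defining "first month" (default 30).
#' @param adjust `"joint"` (BH across all 24 tests) or `"per_metric"` (BH
#'   within each metric's 6 tests).
#' @return A tibble with one row per (metric, subdomain): `metric`,
#'   `bacs_subdomain`, `n`, `rho`, `p_raw`, `p_fdr`.
#' @export
baseline_correlations <- function(analysis_table, roster,
                                  first_month_days = 30,
                                  adjust = c("joint", "per_metric")) {
  adjust <- match.arg(adjust)
  bacs_cols <- bacs_subdomains()
  stopifnot(all(bacs_cols %in% names(roster)))
  mets <- metric_columns()

  first_month <- analysis_table |>
    dplyr::filter(.data$group == "SZ") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(.data$date < min(.data$date) + first_month_days) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(unname(mets)), mean),
                     .groups = "drop")

  joined <- first_month |>
    dplyr::inner_join(roster[, c("participant_id", bacs_cols)],
                      by = "participant_id") |>
    dplyr::filter(dplyr::if_all(dplyr::all_of(bacs_cols), ~ !is.na(.x)))
  if (nrow(joined) < 3) {
    rlang::abort(sprintf(
      "only %d participant(s) have both first-month screen metrics and baseline cognition; need at least 3",
      nrow(joined)))
  }

  res <- tidyr::expand_grid(metric = names(mets), bacs_subdomain = bacs_cols) |>
    dplyr::mutate(purrr::map2_dfr(.data$metric, .data$bacs_subdomain,
      function(m, b) {
        ct <- suppressWarnings(
          cor.test(joined[[mets[[m]]]], joined[[b]],
                   method = "spearman", exact = FALSE))
        tibble::tibble(n = nrow(joined), rho = unname(ct$estimate),
                       p_raw = ct$p.value)
      }))
  if (adjust == "joint") {
    res$p_fdr <- p.adjust(res$p_raw, method = "BH")
  } else {
    res <- res |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_fdr = p.adjust(.data$p_raw, method = "BH")) |>
      dplyr::ungroup()
  }
  res
}

#' Pooled regression of longitudinal cognition on the screen metrics
#'
#' Ordinary least squares of the daily smartphone cognition score on the four
#' daily screen metrics (number of sessions, number of checks, screen time,
#' session time), pooling all participant-days of one diagnostic group where
#' a cognition score is present. Reports the overall F statistic with
#' (4, n - 5) degrees of freedom, its p value, and the adjusted R-squared.
#' Daily observations are pooled without a clustering correction;
#' cluster-robust standard errors are out of scope for the headline fit and
#' the degrees of freedom reflect pooled rows.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @param group `"SZ"` or `"HC"`.
#' @return An object of class `"cognition_fit"`: a list with `group`,
#'   `n_obs`, `coefficients`, `F_stat`, `df_num`, `df_den`, `p_overall`,
#'   `adj_r2`, and the underlying `lm` fit as `model`.
#' @export
cognition_regression <- function(analysis_table, group = c("SZ", "HC")) {
  group <- match.arg(group)
  mets <- unname(metric_columns())
  d <- analysis_table |>
    dplyr::filter(.data$group == !!group, !is.na(.data$cognition)) |>
    dplyr::select(dplyr::all_of(c("cognition", mets)))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(mets) + 2) {
    rlang::abort(sprintf(
      "group %s has only %d complete cognition days; need at least %d",
      group, nrow(d), length(mets) + 2))
  }
  degenerate <- mets[vapply(d[mets], function(v) sd(v) == 0, logical(1))]
  if (length(degenerate) > 0) {
    rlang::abort(sprintf("rank-deficient design: constant predictor(s) %s",
                         paste(degenerate, collapse = ", ")))
  }
  fml <- stats::reformulate(mets, response = "cognition")
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    rlang::abort(sprintf(
      "rank-deficient design: aliased predictor(s) %s",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  s <- summary(fit)
  fs <- s$fstatistic
  structure(list(
    group = group,
    n_obs = nrow(d),
    coefficients = coef(fit),
    F_stat = unname(fs["value"]),
    df_num = as.integer(fs["numdf"]),
    df_den = as.integer(fs["dendf"]),
    p_overall = unname(pf(fs["value"], fs["numdf"], fs["dendf"],
                          lower.tail = FALSE)),
    adj_r2 = s$adj.r.squared,
    model = fit
  ), class = "cognition_fit")
}

#' @export
print.cognition_fit <- function(x, ...) {
  cat(sprintf(
    "Cognition ~ screen metrics (%s): F(%d,%d) = %.2f, p = %.3g, adj R^2 = %.3f, n = %d\n",
    x$group, x$df_num, x$df_den, x$F_stat, x$p_overall, x$adj_r2, x$n_obs))
  invisible(x)
}
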