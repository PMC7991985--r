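#' Configuration of the synthetic-cohort generator
#'
#' Bundles and validates the parameters of the generative model used to
#' emulate a smartphone digital-phenotyping study: a two-group cohort
#' (schizophrenia and healthy controls), a per-day point process of screen
#' sessions with a short-"check"/long-session duration mixture, a twice-weekly
#' survey schedule per instrument with missingness, and a linear coupling of
#' daily symptom scores to daily screen time with per-participant effect
#' heterogeneity.
#'
#' `true_effect` is the standardized slope of the daily symptom score on
#' standardized daily screen time: either a single number applied to every
#' (group, instrument) pair, or a named list with elements `SZ` and `HC`,
#' each a single number or a named vector over instruments. Under the default
#' `effect_scale = "standardized"` the generator works on a unit-variance
#' latent scale and allocates residual day-level variance as
#' `noise_sd * sqrt(max(1 - b^2 - effect_sd^2 - ranef_sd^2, 0.01))`, so that
#' with `noise_sd = 1` the pooled slope of z(score) on z(screen time) equals
#' `true_effect` in expectation. With `effect_scale = "per_hour"` the
#' coupling is `true_effect` raw score points per hour of daily screen time,
#' the scale on which per-participant regressions are fitted.
#'
#' @param seed Integer seed; the same seed reproduces byte-identical output.
#' @param n_sz,n_hc Number of participants with schizophrenia / controls.
#' @param n_days Study length in days.
#' @param sessions_per_day_mean Poisson mean of daily session counts.
#' @param check_fraction Probability a session is a short "check" (< 15 s).
#' @param check_duration_min,check_duration_max Uniform bounds (seconds) of
#'   check durations; the upper bound must stay strictly below 15.
#' @param long_duration_log_mean,long_duration_log_sd Log-scale parameters of
#'   the lognormal excess of long-session durations; a long session lasts
#'   `15 + rlnorm(...)` seconds, so its mass sits at or above 15 s.
#' @param dropout_prob Probability a participant-day records no data at all
#'   (whole-day dropout, the missingness mode the consecutive-day inclusion
#'   filter reacts to).
#' @param day_intensity_sd Log-scale SD of a shared day-level usage-intensity
#'   factor (lognormal, mean 1) that multiplies both the session rate and
#'   long-session durations. Heavy days therefore carry more sessions, more
#'   checks and more screen time at once, reproducing the strong positive
#'   cross-correlation of daily screen metrics seen in real usage logs; 0
#'   disables it.
#' @param survey_prob_per_scheduled_day Probability a scheduled survey is
#'   actually answered.
#' @param true_effect Standardized symptom-on-screen-time slope(s); see
#'   Details.
#' @param effect_sd_between_participants SD of per-participant slope
#'   heterogeneity around `true_effect`.
#' @param ranef_sd SD of the per participant-instrument random intercept
#'   (latent trait), on the standardized scale.
#' @param noise_sd Day-level noise multiplier (standardized scale).
#' @param effect_scale `"standardized"` (default) or `"per_hour"`.
#' @param age_range Integer (min, max) of uniform ages; must straddle 30 so
#'   both age brackets are populated.
#' @param waking_hours Hours (start, end) within which sessions begin.
#' @param start_date First study day.
#' @param tz Study timezone.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed,
                             n_sz = 54, n_hc = 34, n_days = 90,
                             sessions_per_day_mean = 40,
                             check_fraction = 0.5,
                             check_duration_min = 1,
                             check_duration_max = 14.5,
                             long_duration_log_mean = 4,
                             long_duration_log_sd = 1,
                             dropout_prob = 0.1,
                             day_intensity_sd = 0.4,
                             survey_prob_per_scheduled_day = 0.75,
                             true_effect = 0,
                             effect_sd_between_participants = 0,
                             ranef_sd = 0.5,
                             noise_sd = 1,
                             effect_scale = c("standardized", "per_hour"),
                             age_range = c(18, 47),
                             waking_hours = c(8, 23),
                             start_date = as.Date("2023-01-02"),
                             tz = "UTC") {
  effect_scale <- match.arg(effect_scale)
  stopifnot(
    length(seed) == 1, is.finite(seed), abs(seed) < 2^31 - 10,
    n_sz >= 0, n_hc >= 0, n_days >= 1,
    sessions_per_day_mean >= 0,
    check_fraction >= 0, check_fraction <= 1,
    check_duration_min > 0, check_duration_max < 15,
    check_duration_min <= check_duration_max,
    long_duration_log_sd >= 0,
    dropout_prob >= 0, dropout_prob <= 1, day_intensity_sd >= 0,
    survey_prob_per_scheduled_day >= 0, survey_prob_per_scheduled_day <= 1,
    effect_sd_between_participants >= 0, ranef_sd >= 0, noise_sd > 0,
    length(age_range) == 2, age_range[1] < 30, age_range[2] >= 30,
    length(waking_hours) == 2, waking_hours[1] < waking_hours[2],
    waking_hours[2] <= 24
  )
  cfg <- list(
    seed = as.integer(seed), n_sz = as.integer(n_sz), n_hc = as.integer(n_hc),
    n_days = as.integer(n_days),
    sessions_per_day_mean = sessions_per_day_mean,
    check_fraction = check_fraction,
    check_duration_min = check_duration_min,
    check_duration_max = check_duration_max,
    long_duration_log_mean = long_duration_log_mean,
    long_duration_log_sd = long_duration_log_sd,
    dropout_prob = dropout_prob,
    day_intensity_sd = day_intensity_sd,
    survey_prob_per_scheduled_day = survey_prob_per_scheduled_day,
    true_effect = true_effect,
    effect_sd_between_participants = effect_sd_between_participants,
    ranef_sd = ranef_sd, noise_sd = noise_sd, effect_scale = effect_scale,
    age_range = as.integer(age_range), waking_hours = waking_hours,
    start_date = as.Date(start_date), tz = tz
  )
  effect_matrix(cfg)  # validates the true_effect shape
  structure(cfg, class = "synthetic_config")
}

# resolve true_effect into a group x instrument matrix
effect_matrix <- function(cfg) {
  ins <- instrument_ranges()$instrument
  groups <- c("SZ", "HC")
  m <- matrix(0, nrow = 2, ncol = length(ins),
              dimnames = list(groups, ins))
  te <- cfg$true_effect
  if (is.numeric(te) && length(te) == 1) {
    m[] <- te
  } else if (is.list(te)) {
    if (!all(names(te) %in% groups)) {
      rlang::abort("true_effect list names must be 'SZ' and/or 'HC'")
    }
    for (g in names(te)) {
      v <- te[[g]]
      if (length(v) == 1 && is.null(names(v))) {
        m[g, ] <- v
      } else {
        if (!all(names(v) %in% ins)) {
          rlang::abort("true_effect instrument names must be among: mood, anxiety, sleep, social, cognition")
        }
        m[g, names(v)] <- v
      }
    }
  } else {
    rlang::abort("true_effect must be a single number or a named list by group")
  }
  m
}

#' Generate a synthetic participant roster
#'
#' Emulates a two-group smartphone cohort: `n_sz` participants with
#' schizophrenia and `n_hc` healthy controls, ages drawn uniformly from
#' `age_range` (populating both the under-30 and 30-plus brackets whenever
#' the counts allow), gender dominated by male/female with a small share of
#' other. SZ participants carry six baseline BACS subdomain scores (Verbal
#' Memory, Verbal Fluency, Digit Sequencing, Symbol Coding, Token Motor,
#' Tower of London); controls carry none, since the instrument is specific to
#' schizophrenia.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with columns `participant_id`, `group`, `age`, `gender`
#'   and `bacs_*` (NA for controls).
#' @export
generate_roster <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_sz + cfg$n_hc
  if (n < 1) rlang::abort("zero participants requested (n_sz + n_hc == 0)")
  withr::with_seed(cfg$seed + 1L, {
    roster <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = c(rep("SZ", cfg$n_sz), rep("HC", cfg$n_hc)),
      age = sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE),
      gender = sample(c("male", "female", "other"), n, replace = TRUE,
                      prob = c(0.47, 0.47, 0.06))
    )
    # guarantee both age brackets are populated when there is room
    if (n >= 2) {
      if (!any(roster$age < 30)) {
        roster$age[1] <- sample(seq(cfg$age_range[1], 29), 1)
      }
      if (!any(roster$age >= 30)) {
        roster$age[n] <- sample(seq(30, cfg$age_range[2]), 1)
      }
    }
    for (b in bacs_subdomains()) {
      roster[[b]] <- ifelse(roster$group == "SZ",
                            round(rnorm(n, mean = 40, sd = 8), 1), NA_real_)
    }
    roster
  })
}

#' @rdname generate_roster
#' @export
bacs_subdomains <- function() {
  c("bacs_verbal_memory", "bacs_verbal_fluency", "bacs_digit_sequencing",
    "bacs_symbol_coding", "bacs_token_motor", "bacs_tower_of_london")
}

#' Generate a synthetic screen on/off event stream
#'
#' Per participant-day (outside whole-day dropout), draws a Poisson number of
#' sessions; each is a check with probability `check_fraction` (uniform
#' duration strictly under 15 s) or a long session (15 s plus a lognormal
#' excess). Session start times are uniform within waking hours and resampled
#' on overlap so sessions never overlap and every On/Off pair is strictly
#' ordered within a participant. Each session emits one "Screen On" and one
#' "Screen Off" event; timestamps are whole seconds, matching event-log
#' exports.
#'
#' @param cfg A [synthetic_config()].
#' @param roster Output of [generate_roster()].
#' @return A tibble `participant_id`, `timestamp`, `state`, sorted by
#'   participant and time.
#' @export
generate_events <- function(cfg, roster) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (nrow(roster) == 0) rlang::abort("roster is empty")
  withr::with_seed(cfg$seed + 2L, {
    grid <- tidyr::expand_grid(participant_id = roster$participant_id,
                               day = seq_len(cfg$n_days))
    grid <- grid[runif(nrow(grid)) >= cfg$dropout_prob, , drop = FALSE]
    # shared day-level usage intensity: busy days have more sessions AND
    # longer sessions, as in real usage logs
    grid$intensity <- rlnorm(nrow(grid), -cfg$day_intensity_sd^2 / 2,
                             cfg$day_intensity_sd)
    grid$n <- rpois(nrow(grid), cfg$sessions_per_day_mean * grid$intensity)
    grid <- grid[grid$n > 0, , drop = FALSE]
    if (nrow(grid) == 0) {
      return(tibble::tibble(participant_id = character(),
                            timestamp = as.POSIXct(character(), tz = cfg$tz),
                            state = character()))
    }
    ses <- tibble::tibble(
      participant_id = rep(grid$participant_id, grid$n),
      day = rep(grid$day, grid$n),
      intensity = rep(grid$intensity, grid$n)
    )
    m <- nrow(ses)
    is_check <- runif(m) < cfg$check_fraction
    dur <- numeric(m)
    dur[is_check] <- runif(sum(is_check), cfg$check_duration_min,
                           cfg$check_duration_max)
    dur[!is_check] <- 15 +
      rlnorm(sum(!is_check), cfg$long_duration_log_mean,
             cfg$long_duration_log_sd) * ses$intensity[!is_check]
    dur <- pmax(1, round(dur))
    dur[is_check] <- pmin(dur[is_check], 14)  # rounding must not reach 15 s
    w0 <- cfg$waking_hours[1] * 3600
    w1 <- cfg$waking_hours[2] * 3600
    ses$dur <- dur
    ses$start_s <- floor(runif(m, w0, w1))
    ses <- resolve_overlaps(ses, w0, w1)
    # a long session can spill past midnight into the next day's sessions;
    # enforce strict non-overlap across the whole participant stream
    ses <- ses |>
      dplyr::mutate(abs_start = (.data$day - 1) * 86400 + .data$start_s) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(prev_end = dplyr::lag(cummax(.data$abs_start +
                                                   .data$dur))) |>
      dplyr::ungroup() |>
      dplyr::filter(is.na(.data$prev_end) | .data$abs_start > .data$prev_end) |>
      dplyr::select(-"abs_start", -"prev_end")

    base <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = cfg$tz)
    on_t <- base + (ses$day - 1) * 86400 + ses$start_s
    off_t <- on_t + ses$dur
    inter <- as.vector(rbind(as.numeric(on_t), as.numeric(off_t)))
    ev <- tibble::tibble(
      participant_id = rep(ses$participant_id, each = 2),
      timestamp = as.POSIXct(inter, tz = cfg$tz, origin = "1970-01-01"),
      state = rep(c("Screen On", "Screen Off"), nrow(ses))
    )
    dplyr::arrange(ev, .data$participant_id, .data$timestamp)
  })
}

# re-draw start times of overlapping sessions within each participant-day;
# sessions still colliding after max_iter redraws are dropped (a handful per
# million at default densities). A >= 1 s gap is enforced so event
# timestamps are strictly increasing.
resolve_overlaps <- function(ses, w0, w1, max_iter = 30) {
  for (i in seq_len(max_iter)) {
    ses <- ses[order(ses$participant_id, ses$day, ses$start_s), , drop = FALSE]
    new_grp <- c(TRUE, ses$participant_id[-1] != ses$participant_id[-nrow(ses)] |
                   ses$day[-1] != ses$day[-nrow(ses)])
    prev_end <- dplyr::lag(ses$start_s + ses$dur)
    clash <- !new_grp & ses$start_s <= prev_end
    clash[is.na(clash)] <- FALSE
    if (!any(clash)) break
    ses$start_s[clash] <- floor(runif(sum(clash), w0, w1))
  }
  ses <- ses[order(ses$participant_id, ses$day, ses$start_s), , drop = FALSE]
  new_grp <- c(TRUE, ses$participant_id[-1] != ses$participant_id[-nrow(ses)] |
                 ses$day[-1] != ses$day[-nrow(ses)])
  prev_end <- dplyr::lag(ses$start_s + ses$dur)
  clash <- !new_grp & ses$start_s <= prev_end
  clash[is.na(clash)] <- FALSE
  ses[!clash, , drop = FALSE]
}

#' Generate synthetic survey and cognition responses
#'
#' Each instrument is scheduled twice a week (the ten-surveys-per-week
#' protocol: two each of mood, anxiety, sleep, sociability, plus the
#' cognition task); a scheduled response materializes with probability
#' `survey_prob_per_scheduled_day`. The day's score couples linearly to that
#' day's (standardized) screen time through the participant's slope
#' `b_i = true_effect(group, instrument) + N(0, effect_sd^2)`, plus a
#' per participant-instrument random intercept and day-level noise, then is
#' clipped to the instrument range (cognition is unbounded). Responses that
#' land on a day with no screen metrics (dropout days) are generated from
#' noise only and counted in the attached log.
#'
#' @param cfg A [synthetic_config()].
#' @param roster Output of [generate_roster()].
#' @param daily_metrics Output of [daily_metrics()] on the generated events.
#' @return A tibble `participant_id`, `timestamp`, `instrument`, `score`.
#'   The per-participant ground-truth slopes are attached as attribute
#'   `"truth"`; the count of noise-only responses as attribute `"log"`.
#' @export
generate_surveys <- function(cfg, roster, daily_metrics) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (nrow(roster) == 0) rlang::abort("roster is empty")
  rng <- instrument_ranges()
  eff <- effect_matrix(cfg)
  # twice-weekly schedule: weekday slots per instrument
  slots <- list(mood = c(0, 3), anxiety = c(1, 4), sleep = c(2, 5),
                social = c(3, 6), cognition = c(1, 5))

  withr::with_seed(cfg$seed + 3L, {
    x <- daily_metrics |>
      dplyr::mutate(day = as.integer(.data$date - cfg$start_date) + 1L)
    mu_x <- mean(x$screen_time_s)
    sd_x <- sd(x$screen_time_s)
    if (!is.finite(sd_x) || sd_x == 0) sd_x <- 1
    x_lookup <- x |>
      dplyr::transmute(.data$participant_id, .data$day,
                       z_x = (.data$screen_time_s - mu_x) / sd_x,
                       hours = .data$screen_time_s / 3600)

    slot_tbl <- tibble::tibble(
      instrument = rep(names(slots), lengths(slots)),
      wd = unlist(slots, use.names = FALSE)
    )
    sched <- tidyr::expand_grid(
      participant_id = roster$participant_id,
      instrument = rng$instrument,
      day = seq_len(cfg$n_days)
    ) |>
      dplyr::mutate(wd = (.data$day - 1L) %% 7L) |>
      dplyr::inner_join(slot_tbl, by = c("instrument", "wd")) |>
      dplyr::select(-"wd")
    sched <- sched[runif(nrow(sched)) < cfg$survey_prob_per_scheduled_day, ,
                   drop = FALSE]

    # per participant x instrument slopes and random intercepts
    pi_grid <- tidyr::expand_grid(participant_id = roster$participant_id,
                                  instrument = rng$instrument) |>
      dplyr::left_join(roster[, c("participant_id", "group")],
                       by = "participant_id")
    pi_grid$b_pop <- eff[cbind(pi_grid$group, pi_grid$instrument)]
    pi_grid$b_i <- pi_grid$b_pop +
      rnorm(nrow(pi_grid), 0, cfg$effect_sd_between_participants)
    pi_grid$a_i <- rnorm(nrow(pi_grid), 0, cfg$ranef_sd)

    resp <- sched |>
      dplyr::left_join(pi_grid, by = c("participant_id", "instrument")) |>
      dplyr::left_join(x_lookup, by = c("participant_id", "day")) |>
      dplyr::left_join(rng, by = "instrument")
    n_noise_only <- sum(is.na(resp$z_x))
    resp$z_x[is.na(resp$z_x)] <- 0
    resp$hours[is.na(resp$hours)] <- 0

    eps <- rnorm(nrow(resp))
    if (cfg$effect_scale == "standardized") {
      resid_sd <- cfg$noise_sd *
        sqrt(pmax(1 - resp$b_pop^2 - cfg$effect_sd_between_participants^2 -
                    cfg$ranef_sd^2, 0.01))
      y_z <- resp$b_i * resp$z_x + resp$a_i + eps * resid_sd
      score <- resp$midpoint + resp$scale_sd * y_z
    } else {
      score <- resp$midpoint + resp$b_i * resp$hours +
        resp$scale_sd * (resp$a_i + eps * cfg$noise_sd)
    }
    score <- pmin(pmax(score, resp$lower), resp$upper)

    base <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = cfg$tz)
    out <- tibble::tibble(
      participant_id = resp$participant_id,
      timestamp = base + (resp$day - 1) * 86400 +
        floor(runif(nrow(resp), 9 * 3600, 21 * 3600)),
      instrument = resp$instrument,
      score = score
    ) |>
      dplyr::arrange(.data$participant_id, .data$timestamp, .data$instrument)
    if (n_noise_only > 0) {
      rlang::inform(sprintf(
        "generate_surveys: %d response(s) fell on days without screen metrics; generated from noise only",
        n_noise_only))
    }
    attr(out, "truth") <- tibble::as_tibble(
      pi_grid[, c("participant_id", "group", "instrument", "b_pop", "b_i")])
    attr(out, "log") <- list(n_noise_only = n_noise_only)
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Runs roster, event and survey generation end to end (events are
#' sessionized to obtain the daily screen metrics the survey coupling needs)
#' and optionally writes the three standard input CSVs.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional directory; when given, writes `roster.csv`,
#'   `events.csv` and `surveys.csv` there (ISO-8601 timestamps).
#' @return A list with `roster`, `events`, `surveys`, `daily_metrics`, and
#'   `truth` (the per-participant generative slopes).
#' @export
simulate_study <- function(cfg, dir = NULL) {
  roster <- generate_roster(cfg)
  events <- generate_events(cfg, roster)
  sessions <- sessionize(events, tz = cfg$tz, quiet = TRUE)
  dm <- daily_metrics(sessions, tz = cfg$tz)
  surveys <- suppressMessages(generate_surveys(cfg, roster, dm))
  out <- list(roster = roster, events = events, surveys = surveys,
              daily_metrics = dm, truth = attr(surveys, "truth"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(roster, file.path(dir, "roster.csv"))
    ev <- events
    ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S", tz = cfg$tz)
    readr::write_csv(ev, file.path(dir, "events.csv"))
    sv <- surveys
    sv$timestamp <- format(sv$timestamp, "%Y-%m-%dT%H:%M:%S", tz = cfg$tz)
    readr::write_csv(sv, file.path(dir, "surveys.csv"))
  }
  out
}
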