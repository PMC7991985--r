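# Independent oracles used across the suite. These are deliberately written
# as brute-force / closed-form computations that share no code with the
# package internals they check.

# Benjamini-Hochberg step-down: p_(i) * m / i, monotonized from the largest
# rank downward, capped at 1, returned in the input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  cand <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(cand)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# closed-form simple OLS slope
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# longest run of consecutive dates, by brute force over every start date
longest_run_oracle <- function(dates) {
  d <- unique(as.integer(dates))
  if (length(d) == 0) return(0L)
  best <- 0L
  for (s in d) {
    k <- 0L
    while ((s + k) %in% d) k <- k + 1L
    best <- max(best, k)
  }
  best
}

# brute-force per participant-day screen time from a well-formed event
# stream: clip each On->Off interval to every calendar-day window it touches
# and sum. Independent of the package's midnight-splitting code.
daily_screen_oracle <- function(events, tz = "UTC") {
  events <- events[order(events$participant_id, events$timestamp), ]
  out <- list()
  for (pid in unique(events$participant_id)) {
    ev <- events[events$participant_id == pid, ]
    ons <- which(ev$state %in% c("Screen On", "On"))
    for (i in ons) {
      s <- as.numeric(ev$timestamp[i])
      e <- as.numeric(ev$timestamp[i + 1])
      d0 <- lubridate::as_date(lubridate::with_tz(ev$timestamp[i], tz))
      d1 <- lubridate::as_date(lubridate::with_tz(ev$timestamp[i + 1], tz))
      for (d in seq(d0, d1, by = "day")) {
        day_start <- as.numeric(lubridate::force_tz(
          lubridate::as_datetime(as.Date(d, origin = "1970-01-01")), tz))
        day_end <- day_start + 86400
        contrib <- min(e, day_end) - max(s, day_start)
        if (contrib > 0 || (s == e && s >= day_start && s < day_end)) {
          key <- paste(pid, as.Date(d, origin = "1970-01-01"))
          out[[key]] <- (out[[key]] %||% 0) + max(contrib, 0)
        }
      }
    }
  }
  tibble::tibble(
    participant_id = sub(" .*", "", names(out)),
    date = as.Date(sub(".* ", "", names(out))),
    screen_time_s = unlist(out, use.names = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random well-formed event stream (alternating On/Off, strictly increasing
# integer-second timestamps); starts in the evening so some sessions cross
# midnight
random_stream <- function(pid = "P001", n_sessions = 10,
                          base = as.POSIXct("2023-03-01 18:00:00", tz = "UTC"),
                          tz = "UTC") {
  gaps <- sample(1:6000, n_sessions, replace = TRUE)
  durs <- sample(0:8000, n_sessions, replace = TRUE)
  on_t <- base + cumsum(gaps + dplyr::lag(durs, default = 0))
  off_t <- on_t + durs
  tibble::tibble(
    participant_id = pid,
    timestamp = as.POSIXct(as.vector(rbind(as.numeric(on_t),
                                           as.numeric(off_t))),
                           tz = tz, origin = "1970-01-01"),
    state = rep(c("Screen On", "Screen Off"), n_sessions)
  )
}

# minimal analysis-table builder for direct tests of the modelling stages
make_table <- function(n_participants = 20, n_days = 30, seed = 1,
                       effect = 0, group = NULL) {
  withr::with_seed(seed, {
    ids <- sprintf("T%03d", seq_len(n_participants))
    grp <- group %||% rep(c("SZ", "HC"), length.out = n_participants)
    rows <- tidyr::expand_grid(i = seq_len(n_participants),
                               date = as.Date("2023-01-02") +
                                 seq_len(n_days) - 1)
    n <- nrow(rows)
    st <- pmax(60, rnorm(n, 3600, 1200))
    tibble::tibble(
      participant_id = ids[rows$i],
      date = rows$date,
      screen_time_s = st,
      n_sessions = pmax(1L, rpois(n, 20)),
      n_checks = rpois(n, 8),
      mood = 13.5 + effect * scale(st)[, 1] * 4 + rnorm(n, 0, 4),
      anxiety = 10.5 + effect * scale(st)[, 1] * 3 + rnorm(n, 0, 3),
      sleep = 5 + effect * scale(st)[, 1] + rnorm(n, 0, 1.5),
      social = 5 + effect * scale(st)[, 1] + rnorm(n, 0, 1.5),
      cognition = 50 + rnorm(n, 0, 10),
      group = grp[rows$i],
      age_bracket = rep(c("under30", "over30"),
                        length.out = n_participants)[rows$i],
      gender = rep(c("male", "female", "female", "male"),
                   length.out = n_participants)[rows$i]
    ) |>
      dplyr::mutate(session_time_s = screen_time_s / n_sessions,
                    n_checks = pmin(n_checks, n_sessions))
  })
}
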