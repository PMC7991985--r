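test_that("the roster has the configured group sizes, brackets, genders and BACS pattern", {
  cfg <- synthetic_config(seed = 101)
  roster <- generate_roster(cfg)
  expect_equal(nrow(roster), 88)
  expect_equal(sum(roster$group == "SZ"), 54)
  expect_equal(sum(roster$group == "HC"), 34)
  expect_true(any(roster$age < 30) && any(roster$age >= 30))
  expect_true(all(roster$gender %in% c("male", "female", "other")))
  expect_gt(mean(roster$gender %in% c("male", "female")), 0.5)
  bacs <- roster[, bacs_subdomains()]
  expect_true(all(stats::complete.cases(bacs[roster$group == "SZ", ])))
  expect_true(all(is.na(bacs[roster$group == "HC", ])))
})

test_that("degenerate rosters behave: one SZ works, zero participants error", {
  cfg <- synthetic_config(seed = 102, n_sz = 1, n_hc = 0)
  roster <- generate_roster(cfg)
  expect_equal(nrow(roster), 1)
  expect_equal(sum(!is.na(unlist(roster[1, bacs_subdomains()]))), 6)
  expect_error(generate_roster(synthetic_config(seed = 1, n_sz = 0, n_hc = 0)),
               "zero participants")
})

test_that("the same seed reproduces byte-identical output from all three generators", {
  cfg <- synthetic_config(seed = 103, n_sz = 5, n_hc = 5, n_days = 10,
                          sessions_per_day_mean = 8)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$roster, b$roster)
  expect_identical(a$events, b$events)
  expect_identical(a$surveys, b$surveys, ignore_attr = TRUE)
})

test_that("event streams are valid sessionizer input: alternating states, strictly increasing times", {
  cfg <- synthetic_config(seed = 104, n_sz = 4, n_hc = 4, n_days = 12,
                          sessions_per_day_mean = 25)
  ev <- generate_events(cfg, generate_roster(cfg))
  by_pid <- split(ev, ev$participant_id)
  for (d in by_pid) {
    expect_true(all(diff(as.numeric(d$timestamp)) > 0))
    expect_true(all(d$state == rep(c("Screen On", "Screen Off"),
                                   nrow(d) / 2)))
  }
  s <- sessionize(ev, quiet = TRUE)
  expect_equal(attr(s, "log")$n_dropped_on, 0)
  expect_equal(attr(s, "log")$n_dropped_off, 0)
})

test_that("degenerate session mixtures behave as configured", {
  cfg0 <- synthetic_config(seed = 105, n_sz = 3, n_hc = 0, n_days = 5,
                           sessions_per_day_mean = 0)
  expect_equal(nrow(generate_events(cfg0, generate_roster(cfg0))), 0)

  cfg1 <- synthetic_config(seed = 106, n_sz = 3, n_hc = 0, n_days = 10,
                           sessions_per_day_mean = 20, check_fraction = 1)
  s <- sessionize(generate_events(cfg1, generate_roster(cfg1)), quiet = TRUE)
  expect_true(all(s$duration_s < 15))
})

test_that("the empirical check fraction lands within 3 binomial SE of the configured one", {
  cfg <- synthetic_config(seed = 107, n_sz = 4, n_hc = 4, n_days = 10,
                          sessions_per_day_mean = 20, dropout_prob = 0)
  s <- sessionize(generate_events(cfg, generate_roster(cfg)), quiet = TRUE)
  n <- nrow(s)
  expect_gt(n, 1000)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(s$duration_s < 15) - cfg$check_fraction), 3 * se)
})

test_that("a null, noise-free generator emits the instrument midpoint; clipping respects ranges", {
  cfg <- synthetic_config(seed = 108, n_sz = 4, n_hc = 4, n_days = 14,
                          sessions_per_day_mean = 10, true_effect = 0,
                          ranef_sd = 0, noise_sd = 1e-9)
  sim <- simulate_study(cfg)
  mid <- instrument_ranges()
  for (ins in mid$instrument) {
    sc <- sim$surveys$score[sim$surveys$instrument == ins]
    expect_equal(sc, rep(mid$midpoint[mid$instrument == ins], length(sc)),
                 tolerance = 1e-6)
  }

  # strong coupling pushes scores against the bounds; they must stay inside
  cfg2 <- synthetic_config(seed = 109, n_sz = 20, n_hc = 0, n_days = 14,
                           sessions_per_day_mean = 10,
                           true_effect = list(SZ = c(mood = 0.9)),
                           ranef_sd = 3, noise_sd = 3)
  sim2 <- simulate_study(cfg2)
  mood <- sim2$surveys$score[sim2$surveys$instrument == "mood"]
  expect_true(all(mood >= 0 & mood <= 27))
  expect_true(any(mood == 27 | mood == 0))  # clipping actually engaged
})

test_that("the pooled standardized slope recovers the generative effect", {
  cfg <- synthetic_config(seed = 110, n_sz = 100, n_hc = 100, n_days = 28,
                          sessions_per_day_mean = 25, true_effect = 0.5,
                          dropout_prob = 0)
  sim <- simulate_study(cfg)
  ds <- aggregate_daily(sim$surveys, quiet = TRUE)
  tbl <- sim$daily_metrics |>
    dplyr::left_join(ds, by = c("participant_id", "date"))
  long <- tbl |>
    tidyr::pivot_longer(dplyr::all_of(instrument_ranges()$instrument),
                        names_to = "instrument", values_to = "score") |>
    dplyr::filter(!is.na(score)) |>
    dplyr::group_by(instrument) |>
    dplyr::mutate(zy = as.numeric(scale(score)),
                  zx = as.numeric(scale(screen_time_s))) |>
    dplyr::ungroup()
  slope <- slope_oracle(long$zx, long$zy)
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("with a null effect the screen-symptom correlation shrinks toward zero as n grows", {
  pooled_cor <- function(seed, n_per_group) {
    cfg <- synthetic_config(seed = seed, n_sz = n_per_group,
                            n_hc = n_per_group, n_days = 21,
                            sessions_per_day_mean = 15, true_effect = 0)
    sim <- simulate_study(cfg)
    ds <- aggregate_daily(sim$surveys, quiet = TRUE)
    tbl <- dplyr::left_join(sim$daily_metrics, ds,
                            by = c("participant_id", "date"))
    d <- tbl[!is.na(tbl$mood), ]
    cor(d$screen_time_s, d$mood)
  }
  small <- mean(abs(vapply(111:115, pooled_cor, numeric(1), n_per_group = 4)))
  large <- mean(abs(vapply(111:115, pooled_cor, numeric(1), n_per_group = 60)))
  expect_lt(large, 0.05)
  expect_lt(large, small)
})

test_that("invalid configurations are refused", {
  expect_error(synthetic_config(seed = 1, check_fraction = 1.2))
  expect_error(synthetic_config(seed = 1, check_duration_max = 15))
  expect_error(synthetic_config(seed = 1, noise_sd = 0))
  expect_error(synthetic_config(seed = 1, age_range = c(31, 40)))
  expect_error(synthetic_config(seed = 1,
                                true_effect = list(BAD = 0.2)))
})

test_that("simulate_study writes the three standard CSV inputs that round-trip", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 112, n_sz = 3, n_hc = 2, n_days = 8,
                          sessions_per_day_mean = 6)
  sim <- simulate_study(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("roster.csv", "events.csv", "surveys.csv")))))
  ev <- read_events(file.path(dir, "events.csv"))
  expect_equal(nrow(ev), nrow(sim$events))
  expect_identical(as.numeric(ev$timestamp), as.numeric(sim$events$timestamp))
  ro <- read_roster(file.path(dir, "roster.csv"))
  expect_equal(ro$participant_id, sim$roster$participant_id)
})
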