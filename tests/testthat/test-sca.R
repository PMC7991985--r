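test_that("the default grid enumerates 576 unique specifications in deterministic order", {
  g <- build_grid()
  expect_equal(nrow(g), 576)
  expect_equal(anyDuplicated(g[, -1]), 0)
  expect_identical(g, build_grid())            # pure function
  # lexicographic: x varies slowest, subset_age fastest
  expect_equal(g$x[1:144], rep("screen_time", 144))
  expect_equal(g$subset_age[1:3], c("under30", "over30", "all"))
})

test_that("menu variations produce the expected combinatorial counts", {
  g256 <- build_grid(list(subset_group = c("SZ", "HC"),
                          subset_age = c("under30", "over30")))
  expect_equal(nrow(g256), 256)
  g1 <- build_grid(list(x = "screen_time", y = "mood", model = "linear",
                        covariates = "none", subset_group = "all",
                        subset_age = "all"))
  expect_equal(nrow(g1), 1)
  expect_error(build_grid(list(x = character(0))), "empty")
  expect_error(build_grid(list(x = c("screen_time", "screen_time"))),
               "duplicates")
  expect_error(build_grid(list(y = "happiness")), "unknown")
})

test_that("an identity relationship is recovered as estimate 1 after standardization", {
  tbl <- make_table(n_participants = 10, n_days = 20, seed = 41)
  tbl$mood <- tbl$screen_time_s / 1000  # exact monotone-linear copy
  spec <- build_grid(list(x = "screen_time", y = "mood", model = "linear",
                          covariates = "none", subset_group = "all",
                          subset_age = "all"))
  res <- suppressWarnings(fit_spec(spec[1, ], tbl))
  expect_equal(res$status, "fit")
  expect_equal(res$estimate, 1)
})

test_that("degenerate subsets are reported, not silently fitted", {
  tbl <- make_table(n_participants = 8, n_days = 15, seed = 42)
  spec <- build_grid(list(x = "n_checks", y = "mood", model = "linear",
                          covariates = "none", subset_group = "all",
                          subset_age = "all"))
  tbl$n_checks <- 4L                         # constant predictor
  res <- fit_spec(spec[1, ], tbl)
  expect_equal(res$status, "failed")
  expect_match(res$message, "constant")

  tbl2 <- make_table(n_participants = 2, n_days = 3, seed = 43)
  res2 <- fit_spec(spec[1, ], tbl2, min_n = 10)
  expect_equal(res2$status, "skipped_small_n")
  expect_true(is.na(res2$estimate))
})

test_that("gaussian-identity GLM and the linear model agree on every spec", {
  tbl <- make_table(n_participants = 16, n_days = 25, seed = 44)
  g <- build_grid()
  lin <- g[g$model == "linear", ]
  glm_ <- g[g$model == "generalized_linear", ]
  for (i in seq_len(nrow(lin))) {
    a <- fit_spec(lin[i, ], tbl)
    b <- fit_spec(glm_[i, ], tbl)
    expect_equal(a$status, b$status)
    if (a$status == "fit") {
      expect_lt(abs(a$estimate - b$estimate), 1e-8)
      expect_lt(abs(a$p - b$p), 1e-8)
    }
  }
})

test_that("simple linear specs equal the closed-form standardized slope oracle", {
  withr::with_seed(45, {
    tbl <- make_table(n_participants = 12, n_days = 20, seed = 45,
                      effect = 0.3)
    g <- build_grid(list(model = "linear", covariates = "none"))
    picks <- g[sample(nrow(g), 25), ]
    mets <- c(screen_time = "screen_time_s", session_time = "session_time_s",
              n_checks = "n_checks", n_sessions = "n_sessions")
    for (i in seq_len(nrow(picks))) {
      sp <- picks[i, ]
      res <- fit_spec(sp, tbl)
      if (res$status != "fit") next
      d <- tbl
      if (sp$subset_group != "all") d <- d[d$group == sp$subset_group, ]
      if (sp$subset_age != "all") d <- d[d$age_bracket == sp$subset_age, ]
      d <- d[!is.na(d[[mets[[sp$x]]]]) & !is.na(d[[sp$y]]), ]
      zx <- as.numeric(scale(d[[mets[[sp$x]]]]))
      zy <- as.numeric(scale(d[[sp$y]]))
      expect_equal(res$estimate, slope_oracle(zx, zy))
    }
  })
})

test_that("participants with gender other are dropped only from gender-covariate specs", {
  tbl <- make_table(n_participants = 9, n_days = 10, seed = 46)
  tbl$gender[tbl$participant_id == "T001"] <- "other"
  base <- build_grid(list(x = "screen_time", y = "mood", model = "linear",
                          subset_group = "all", subset_age = "all"))
  no_cov <- fit_spec(base[base$covariates == "none", ], tbl)
  with_cov <- fit_spec(base[base$covariates == "gender", ], tbl)
  expect_equal(no_cov$n_participants, 9)
  expect_equal(with_cov$n_participants, 8)
  expect_equal(no_cov$n_obs - with_cov$n_obs, 10)
})

test_that("run_sca is deterministic, records per-spec failures, and its summary is coherent", {
  tbl <- make_table(n_participants = 14, n_days = 20, seed = 47)
  g <- build_grid(list(model = "linear"))
  run1 <- run_sca(g, tbl)
  run2 <- run_sca(g, tbl)
  expect_identical(run1$results, run2$results)
  s <- run1$summary
  expect_equal(s$n_fit + s$n_skipped + s$n_failed, s$n_specs)
  expect_equal(s$share_positive + s$share_negative + s$share_zero, 1)
  expect_true(s$min_estimate <= s$median_estimate &
                s$median_estimate <= s$max_estimate)
  # singleton grid: min = max = the single estimate
  g1 <- build_grid(list(x = "screen_time", y = "mood", model = "linear",
                        covariates = "none", subset_group = "all",
                        subset_age = "all"))
  run3 <- run_sca(g1, tbl)
  expect_equal(run3$summary$min_estimate, run3$summary$max_estimate)
  expect_equal(run3$summary$min_estimate, run3$results$estimate[1])
})

test_that("under a null generator the curve is centred on zero and sign-balanced", {
  ests <- purrr::map_dfr(1:6, function(r) {
    cfg <- synthetic_config(seed = 480 + r, n_sz = 12, n_hc = 12,
                            n_days = 28, sessions_per_day_mean = 15,
                            true_effect = 0)
    sim <- simulate_study(cfg)
    ds <- aggregate_daily(sim$surveys, quiet = TRUE)
    flt <- filter_cohort(sim$roster, sim$daily_metrics, ds)
    tbl <- build_analysis_table(flt$included, sim$daily_metrics, ds)
    run_sca(build_grid(list(model = "linear")), tbl)$results
  })
  fitted <- ests[ests$status == "fit", ]
  expect_gt(nrow(fitted), 500)
  expect_lt(abs(median(fitted$estimate)), 0.05)
  expect_gt(mean(fitted$estimate > 0), 0.40)
  expect_lt(mean(fitted$estimate > 0), 0.60)
})

test_that("the curve plot sorts estimates ascending and marks every choice dimension", {
  tbl <- make_table(n_participants = 14, n_days = 20, seed = 49)
  run <- run_sca(build_grid(list(model = "linear", covariates = "none")), tbl)
  p <- plot_curve(run)
  panels <- if (inherits(p, "patchwork")) list(p[[1]], p[[2]]) else p
  est_data <- ggplot2::ggplot_build(panels[[1]])$data[[1]]
  ord <- est_data$y[order(est_data$x)]
  expect_true(all(diff(ord) >= 0))
  ind <- panels[[2]]$data
  marks_per_rank <- table(ind$rank)
  expect_true(all(marks_per_rank == 6))
  expect_error(plot_curve(run$results[run$results$status != "fit", ]),
               "no fitted")
})
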