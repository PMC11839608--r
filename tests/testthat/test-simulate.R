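test_that("runs are bit-reproducible and degenerate cleanly at horizon 0", {
  cfg <- simulation_config(horizon = 8, n = 2, seed = 1, policy = "random")
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$summary, r2$summary)
  r0 <- run_simulation(simulation_config(horizon = 0, n = 2, seed = 1))
  expect_equal(nrow(r0$timeseries), 0)
  expect_equal(r0$summary$mean_engagement, 0)
  expect_equal(r0$summary$cumulative_reward, 0)
})

test_that("engagement and adherence stay within [0, 1] for every policy", {
  for (pol in c("random", "pid_only", "rl", "rl_feedback")) {
    r <- run_simulation(simulation_config(horizon = 10, n = 2, seed = 4,
                                          policy = pol))
    expect_true(all(r$timeseries$engagement >= 0 & r$timeseries$engagement <= 1))
    expect_true(all(r$timeseries$adherence >= 0 & r$timeseries$adherence <= 1))
    expect_true(all(is.finite(r$timeseries$fitness)))
  }
})

test_that("summary statistics are recomputable from the emitted time series", {
  r <- run_simulation(simulation_config(horizon = 12, n = 3, seed = 9,
                                        policy = "rl"))
  ts <- r$timeseries
  expect_equal(r$summary$mean_engagement, mean(ts$engagement))
  expect_equal(r$summary$cumulative_reward, sum(ts$reward))
  expect_equal(r$summary$constraint_violations, sum(ts$engagement < 0.2))
  coh <- vapply(split(ts, ts$t), function(d) {
    cohesion_loss(cbind(d$fitness, d$engagement, d$adherence))
  }, numeric(1))
  expect_equal(r$summary$mean_cohesion, mean(coh))
  expect_equal(r$summary$mental_health_index,
               mental_health_index(ts$emotion_observed))
})

test_that("mental health index is an occupancy-weighted mean", {
  w <- c(STRESS_ANXIETY = 0, OVERLOAD_FATIGUE = 0, LACK_OF_INTEREST = 0,
         RELAX_LOW_ENGAGEMENT = 0, FOCUS = 1, NONE = 0)
  expect_equal(mental_health_index(rep("FOCUS", 10), w), 1.0)
  wu <- c(STRESS_ANXIETY = 0.3, OVERLOAD_FATIGUE = 0.3,
          LACK_OF_INTEREST = 0.3, RELAX_LOW_ENGAGEMENT = 0.3, FOCUS = 0.3,
          NONE = 0.3)
  expect_equal(mental_health_index(emotion_states(), wu), 0.3)
  hist <- c(rep("STRESS_ANXIETY", 6), rep("FOCUS", 4))
  expect_equal(mental_health_index(hist, w), 0.4)
  expect_error(mental_health_index(character(0)),
               class = "apeo_invalid_argument")
})

test_that("reports round-trip through disk byte-identically", {
  r <- run_simulation(simulation_config(horizon = 5, n = 2, seed = 2,
                                        policy = "random"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- report(r, d1)
  f2 <- report(r, d2)
  expect_identical(readLines(f1[["timeseries"]]), readLines(f2[["timeseries"]]))
  expect_identical(readLines(f1[["summary"]]), readLines(f2[["summary"]]))
  back <- jsonlite::read_json(f1[["summary"]], simplifyVector = TRUE)
  expect_equal(back$mean_engagement, r$summary$mean_engagement,
               tolerance = 1e-15)
  expect_equal(back$cumulative_reward, r$summary$cumulative_reward,
               tolerance = 1e-15)
  # empty run still writes valid files
  r0 <- run_simulation(simulation_config(horizon = 0, n = 1, seed = 1))
  f0 <- report(r0, withr::local_tempdir())
  ts0 <- readr::read_csv(f0[["timeseries"]], show_col_types = FALSE)
  expect_equal(nrow(ts0), 0)
})

test_that("config validation rejects unknown keys and bad values", {
  expect_error(simulation_config(eeg = list(duration = 2, sampling = 9)),
               class = "apeo_config_error")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("horizon: 5", "plicy: rl"), tmp)
  expect_error(read_simulation_config(tmp), regexp = "plicy",
               class = "apeo_config_error")
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("horizon: 4", "n: 2", "seed: 3", "policy: random"), tmp2)
  cfg <- read_simulation_config(tmp2)
  expect_equal(cfg$horizon, 4L)
  expect_equal(cfg$policy, "random")
})

test_that("tidiers and autoplot methods cover the main result types", {
  r <- run_simulation(simulation_config(horizon = 4, n = 2, seed = 2,
                                        policy = "random"))
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_equal(g$policy, "random")
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(autoplot(synthesize_eeg("REST", duration = 2, fs = 128)),
                  "ggplot")
  fit <- optimize_forces(3, 1, 0.3, max_iter = 5)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(tidy(fit), "tbl_df")
})
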