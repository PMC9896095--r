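# run a one-arm cohort whose endpoint lands where we want it, by choosing
# flat utilities and a single-cycle cost
arm_trace <- function(u, cost, arm = "index", discount_rate = 0.03) {
  spec <- model_spec(
    make_utilities(u_index = u, u_control = u, u_rec = u, u_nonrec = u),
    make_costs(c(cost, rep(0, 31)), group = arm),
    make_transitions(rep(0, 31), group = arm),
    discount_rate = discount_rate
  )
  run_cohort(spec, arm)
}

test_that("dominance quadrant logic is exhaustive and mutually exclusive", {
  cases <- expand.grid(du = c(-0.1, 0, 0.1), dc = c(-1000, 0, 1000))
  for (k in seq_len(nrow(cases))) {
    du <- cases$du[k]; dc <- cases$dc[k]
    res <- incremental_analysis(arm_trace(0.6 + du / 8, 5000 + dc),
                                arm_trace(0.6, 5000, arm = "control"))
    expected <- if (du > 0 && dc < 0) "dominant"
    else if (du < 0 && dc > 0) "dominated"
    else if (du == 0 && dc == 0) "equivalent"
    else if (du == 0) "undefined"
    else "icer"
    expect_equal(res$verdict, expected)
    if (expected == "icer") {
      expect_equal(res$icer, res$delta_cost_sek / res$delta_qaly)
    }
    if (expected == "undefined") expect_true(is.na(res$icer))
  }
})

test_that("incremental endpoints match hand arithmetic", {
  # identical traces, equal baselines: exact zeros
  res <- incremental_analysis(arm_trace(0.7, 3000),
                              arm_trace(0.7, 3000, arm = "control"),
                              baseline_utilities = c(index = 0.6, control = 0.6))
  expect_equal(res$delta_qaly, 0)
  expect_equal(res$delta_cost_sek, 0)
  expect_equal(res$verdict, "equivalent")

  # +10,000 SEK for +0.5 QALY -> ICER 20,000 SEK/QALY
  res <- incremental_analysis(arm_trace(0.6 + 0.5 / 8, 15000),
                              arm_trace(0.6, 5000, arm = "control"))
  expect_equal(res$delta_qaly, 0.5, tolerance = 1e-9)
  expect_equal(res$delta_cost_sek, 10000, tolerance = 1e-9)
  expect_equal(res$icer, 20000, tolerance = 1e-9)

  # cheaper and more effective -> dominant
  res <- incremental_analysis(arm_trace(0.7, 3000),
                              arm_trace(0.65, 40000, arm = "control"))
  expect_equal(res$verdict, "dominant")
  expect_equal(res$verdict_disc, "dominant")
})

test_that("baseline adjustment is a difference in differences", {
  t_i <- arm_trace(0.75, 1000)
  t_c <- arm_trace(0.70, 1000, arm = "control")
  unadj <- incremental_analysis(t_i, t_c)
  adj <- incremental_analysis(t_i, t_c,
                              baseline_utilities = c(index = 0.62, control = 0.60))
  expect_equal(adj$delta_qaly, unadj$delta_qaly - 0.02 * 8, tolerance = 1e-9)

  # shifting one arm's baseline and its whole trace by a constant changes nothing
  c_shift <- 0.05
  shifted <- incremental_analysis(
    arm_trace(0.75 + c_shift, 1000), t_c,
    baseline_utilities = c(index = 0.62 + c_shift, control = 0.60)
  )
  expect_equal(shifted$delta_qaly, adj$delta_qaly, tolerance = 1e-9)
  expect_equal(shifted$delta_qaly_disc, adj$delta_qaly_disc, tolerance = 1e-9)
})

test_that("mean cost per participant uses individual totals and a seeded bootstrap", {
  # all costs equal: mean c, zero-width interval
  records <- make_cohort(list(A = c("N"), B = c("N"), C = c("N")), cost = 700)
  res <- mean_cost_per_participant(records, "index", boot_reps = 200, seed = 1)
  expect_equal(res$mean_sek, 700)
  expect_equal(unname(res$ci), c(700, 700))

  # explicit denominator overrides the participant count
  res40 <- mean_cost_per_participant(records, "index", denominator = 2,
                                     boot_reps = 50, seed = 1)
  expect_equal(res40$mean_sek, 700 * 3 / 2)

  expect_error(mean_cost_per_participant(records, "control"), "no participants")

  # same seed, same interval; different seed may differ
  sim <- simulate_trial(sim_config(n_index = 30, n_control = 30, seed = 4))
  a <- mean_cost_per_participant(sim$records, "index", boot_reps = 500, seed = 10)
  b <- mean_cost_per_participant(sim$records, "index", boot_reps = 500, seed = 10)
  expect_identical(a$ci, b$ci)
})

test_that("bootstrap interval covers the true mean at roughly nominal rate", {
  set.seed(99)
  true_mean <- 2000
  hits <- 0
  reps <- 120
  for (i in 1:reps) {
    x <- rlnorm(60, meanlog = log(true_mean) - 0.18, sdlog = 0.6)
    records <- make_record()[0, ]
    records <- dplyr::bind_rows(records, tibble::tibble(
      participant_id = sprintf("P%02d", 1:60), group = "index",
      period_start_month = 0, period_end_month = 3,
      treatment_category = "physiotherapy", cost_sek = x,
      utility = NA_real_, untreated_nonrecovered_flag = FALSE
    ))
    res <- mean_cost_per_participant(records, "index", boot_reps = 400,
                                     seed = 1000 + i)
    hits <- hits + (res$ci[1] <= true_mean && true_mean <= res$ci[2])
  }
  # percentile bootstrap on skewed data: coverage near but below 95%
  expect_gt(hits / reps, 0.85)
  expect_lte(hits / reps, 1)
})

test_that("validation compares predicted and observed recovery percentages", {
  obs <- tibble::tibble(month = c(3, 6, 12, 96),
                        percent_recovered = c(0, 58, 65, 68))
  # identical curves: max diff 0, valid
  v <- validate_model(obs, obs)
  expect_equal(v$max_abs_diff, 0)
  expect_true(v$valid)

  # planted 10-point discrepancy at one follow-up with 5-point tolerance
  pred <- obs
  pred$percent_recovered[3] <- 75
  v <- validate_model(pred, obs, tolerance_pct = 5)
  expect_equal(v$max_abs_diff, 10)
  expect_false(v$valid)

  # mismatched grids are rejected
  expect_error(validate_model(pred[-1, ], obs), "grid")
})

test_that("model driven by panel-estimated probabilities validates exactly", {
  sim <- simulate_trial(sim_config(seed = 21))
  panel <- build_state_panel(sim$records)
  transitions <- estimate_transitions(panel, method = "net")
  costs <- estimate_cost_schedule(sim$records, panel)
  spec <- model_spec(model_utilities(panel), costs, transitions)
  for (arm in c("index", "control")) {
    v <- validate_model(predicted_recovery_curve(run_cohort(spec, arm)),
                        observed_recovery(panel, arm))
    expect_equal(v$max_abs_diff, 0, tolerance = 1e-9)
    expect_true(v$valid)
  }
})

test_that("2-SD rule excludes exactly the planted outliers and lowers the mean", {
  # 20 cheap participants and 2 planted extremes in the control arm
  states <- rep(list(c("N", "R", "R", "R")), 22)
  names(states) <- sprintf("C%02d", 1:22)
  records <- make_cohort(states, group = "control", cost = 1000)
  records$cost_sek[records$participant_id %in% c("C21", "C22") &
                     records$treatment_category != "none"] <- 60000
  res <- sensitivity_two_sd(records, boot_reps = 200, seed = 2)
  expect_setequal(res$excluded_ids, c("C21", "C22"))
  expect_lt(res$after$mean_sek, res$before$mean_sek)
  expect_equal(res$after$mean_sek, 1000)

  # excluded individuals always sit above the pooled mean
  expect_true(all(60000 > res$pooled_mean_sek))
})

test_that("2-SD rule with no outliers reproduces the primary result bit-for-bit", {
  # totals 1000..1500: the largest sits well inside mean + 2 SD
  records <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:6),
    group = rep(c("index", "control"), each = 3),
    period_start_month = 0, period_end_month = 3,
    treatment_category = "physiotherapy",
    cost_sek = seq(1000, 1500, by = 100),
    utility = NA_real_, untreated_nonrecovered_flag = FALSE
  )
  res <- sensitivity_two_sd(records, boot_reps = 300, seed = 3)
  expect_length(res$excluded_ids, 0)
  expect_identical(res$before, res$after)
  primary <- mean_cost_per_participant(records, "index", boot_reps = 300,
                                       seed = 3)
  expect_identical(res$before$mean_sek[res$before$group == "index"],
                   primary$mean_sek)
  expect_identical(res$before$ci_lo[res$before$group == "index"],
                   primary$ci[1])

  # property over seeds: no excluded individual lies at or below the pooled mean
  for (seed in 1:5) {
    s <- simulate_trial(sim_config(n_index = 25, n_control = 25, seed = seed))
    r <- sensitivity_two_sd(s$records, boot_reps = 50, seed = seed)
    totals <- participant_cost_totals(s$records)
    excl <- totals$total_cost_sek[totals$participant_id %in% r$excluded_ids]
    expect_true(all(excl > r$pooled_mean_sek))
    after_means <- r$after$mean_sek
    expect_true(all(after_means <= r$before$mean_sek + 1e-9))
  }
})

test_that("degenerate zero-SD costs warn and exclude nobody", {
  records <- make_cohort(list(A = c("N"), B = c("N"), C = c("N")), cost = 500)
  expect_warning(res <- sensitivity_two_sd(records, boot_reps = 50, seed = 1),
                 "SD = 0")
  expect_length(res$excluded_ids, 0)
})
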