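test_that("identical seeds give identical output, different seeds differ", {
  a <- simulate_trial(sim_config(seed = 123))
  b <- simulate_trial(sim_config(seed = 123))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$states, b$truth$states)
  c <- simulate_trial(sim_config(seed = 124))
  expect_false(identical(a$records, c$records))
})

test_that("generated records always satisfy the record invariants", {
  for (seed in c(1, 8, 15)) {
    sim <- simulate_trial(sim_config(seed = seed))
    rec <- sim$records
    # validate_records() already ran inside the generator; spot-check the
    # substantive invariants directly
    expect_true(all(rec$cost_sek[rec$treatment_category == "none"] == 0))
    expect_true(all(rec$cost_sek >= 0))
    expect_true(all(rec$utility >= 0 & rec$utility <= 1))
    expect_true(all(!rec$untreated_nonrecovered_flag |
                      rec$treatment_category == "none"))
    # everyone treated during the per-protocol window
    w1 <- rec[rec$period_end_month == 3, ]
    expect_true(all(w1$treatment_category != "none"))
    expect_true(all(w1$treatment_category[w1$group == "index"] == "specialised_MT"))
  }
})

test_that("zero recovery probability keeps the whole cohort non-recovered", {
  tr <- default_sim_transitions()
  tr$p_recover <- 0
  tr$p_relapse <- 0
  sim <- simulate_trial(sim_config(transitions = tr, seed = 3))
  panel <- build_state_panel(sim$records)
  expect_false(any(panel$cells$category %in%
                     c("recovered_no_treatment", "not_recovered_no_treatment")))
  for (fu in c(3, 6, 12, 96)) {
    expect_equal(recovery_proportion(panel, "index", fu), 0)
  }
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(dropout_prob = 1), "dropout")
  bad_tr <- default_sim_transitions()
  bad_tr$p_recover[1] <- 1.4
  expect_error(sim_config(transitions = bad_tr), "probabilities")
  expect_error(sim_config(n_index = 0), "cohort sizes")
  expect_error(sim_config(cost_sdlog = -1), "dispersions")
})

test_that("estimation recovers the generating parameters on large cohorts", {
  cfg <- sim_config(n_index = 2000, n_control = 2000, seed = 42,
                    dropout_prob = 0)
  sim <- simulate_trial(cfg)
  panel <- build_state_panel(sim$records)
  spans <- attr(estimate_transitions(panel, method = "flows"), "spans")
  truth <- dplyr::filter(sim$truth$states, enrolled)

  # transition probabilities within 3 binomial SE of the generating values
  for (k in seq_len(nrow(cfg$transitions))) {
    g <- cfg$transitions[k, ]
    at_risk <- sum(truth$group == g$group & truth$follow_up == g$from_month &
                     truth$state == "non_recovered")
    est <- spans$p_recover[spans$group == g$group &
                             spans$from_month == g$from_month]
    se <- sqrt(g$p_recover * (1 - g$p_recover) / at_risk)
    expect_lt(abs(est - g$p_recover), max(3 * se, 1e-12) + 1e-12)
  }

  # state utilities within 3 SE of the generating means
  u_cfg <- cfg$utilities
  rec_cells <- dplyr::filter(panel$cells, follow_up > 3,
                             category == "recovered_no_treatment")
  u_rec <- weighted_utility(rec_cells$mean_utility, rec_cells$count,
                            digits = NULL)
  n_rec <- sum(rec_cells$count)
  expect_lt(abs(u_rec - u_cfg$recovered_mean),
            3 * u_cfg$recovered_sd / sqrt(n_rec) + 0.002)  # truncation bias

  # per-period mean treatment costs within 3 SE (log-normal, known CV)
  treated <- dplyr::filter(sim$records, treatment_category == "physiotherapy")
  target <- cfg$cost_means[["physiotherapy"]]
  cv <- sqrt(exp(cfg$cost_sdlog^2) - 1)
  se_cost <- target * cv / sqrt(nrow(treated))
  expect_lt(abs(mean(treated$cost_sek) - target), 3 * se_cost)
})

test_that("identical-arm simulation centres incremental endpoints on zero", {
  tr <- default_sim_transitions()
  tr$p_recover <- rep(c(0.5, 0.3, 0.1), 2)
  tr$p_relapse <- rep(c(0, 0, 0.05), 2)
  dq <- dc <- numeric(0)
  for (seed in 1:8) {
    cfg <- sim_config(
      n_index = 100, n_control = 100, transitions = tr, seed = seed,
      utilities = list(protocol_index = 0.7, protocol_control = 0.7,
                       protocol_sd = 0.08, recovered_mean = 0.81,
                       recovered_sd = 0.1, non_recovered_mean = 0.67,
                       non_recovered_sd = 0.12),
      protocol_category_probs = list(index = c(physiotherapy = 1),
                                     control = c(physiotherapy = 1)),
      post_category_probs = list(index = c(physiotherapy = 1),
                                 control = c(physiotherapy = 1))
    )
    sim <- simulate_trial(cfg)
    panel <- build_state_panel(sim$records)
    spec <- model_spec(model_utilities(panel),
                       estimate_cost_schedule(sim$records, panel),
                       estimate_transitions(panel, method = "net"))
    econ <- incremental_analysis(run_cohort(spec, "index"),
                                 run_cohort(spec, "control"))
    dq <- c(dq, econ$delta_qaly)
    dc <- c(dc, econ$delta_cost_sek)
  }
  # mean incremental endpoints indistinguishable from 0 across seeds
  expect_lt(abs(mean(dq)), 3 * sd(dq) / sqrt(length(dq)) + 1e-9)
  expect_lt(abs(mean(dc)), 3 * sd(dc) / sqrt(length(dc)) + 1e-9)
})
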