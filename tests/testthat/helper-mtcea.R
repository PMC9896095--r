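# Builders for small record sets and an individual-level oracle for the
# cohort engine.

make_record <- function(participant_id = "P1", group = "index",
                        period_start_month = 0, period_end_month = 3,
                        treatment_category = "none", cost_sek = 0,
                        utility = NA_real_,
                        untreated_nonrecovered_flag = FALSE) {
  tibble::tibble(
    participant_id = participant_id, group = group,
    period_start_month = period_start_month,
    period_end_month = period_end_month,
    treatment_category = treatment_category, cost_sek = cost_sek,
    utility = utility,
    untreated_nonrecovered_flag = untreated_nonrecovered_flag
  )
}

# One record per participant x follow-up window from compact per-window
# state specs: states is a list id -> c("N","R","F","N", ...) over windows
# (N treated, R recovered, F recovered-for-costs but flagged symptomatic).
# Treated windows cost `cost`; utilities fixed per state for easy tallies.
make_cohort <- function(states, group = "index", cost = 1000,
                        u = c(N = 0.6, R = 0.8, F = 0.65)) {
  fus <- c(3, 6, 12, 96)
  starts <- c(0, 3, 6, 12)
  rows <- lapply(names(states), function(id) {
    st <- states[[id]]
    lapply(seq_along(st), function(w) {
      make_record(
        participant_id = id, group = group,
        period_start_month = starts[w], period_end_month = fus[w],
        treatment_category = if (st[w] == "N") "physiotherapy" else "none",
        cost_sek = if (st[w] == "N") cost else 0,
        utility = unname(u[st[w]]),
        untreated_nonrecovered_flag = st[w] == "F"
      )
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}

# simple utility_set constructor for engine tests
make_utilities <- function(u_index = 0.7, u_control = 0.7,
                           u_rec = 0.8, u_nonrec = 0.6) {
  structure(
    list(u_index_protocol = u_index, u_control_protocol = u_control,
         u_recovered = u_rec, u_non_recovered = u_nonrec),
    class = "utility_set"
  )
}

make_costs <- function(values, group = "index") {
  structure(
    tibble::tibble(group = group, cycle = seq_along(values),
                   cost_per_nonrecovered = values),
    class = c("cost_schedule", "tbl_df", "tbl", "data.frame")
  )
}

make_transitions <- function(p_recover, p_relapse = 0, group = "index") {
  n <- length(p_recover)
  structure(
    tibble::tibble(group = group, cycle = seq_len(n),
                   p_recover = p_recover,
                   p_relapse = rep_len(p_relapse, n)),
    class = c("transition_schedule", "tbl_df", "tbl", "data.frame")
  )
}

make_spec <- function(p_recover, p_relapse = 0, costs = NULL, arm = "index",
                      n_cycles = NULL, ...) {
  if (is.null(n_cycles)) n_cycles <- length(p_recover) + 1
  if (is.null(costs)) costs <- rep(0, n_cycles)
  model_spec(
    make_utilities(),
    make_costs(costs, group = arm),
    make_transitions(p_recover, p_relapse, group = arm),
    horizon = n_cycles * 3,
    ...
  )
}

# Individual-level microsimulation oracle: n independent participants follow
# the same per-cycle transition probabilities; utilities and costs are the
# deterministic state values, so the only Monte-Carlo noise is in the state
# paths. Means over participants estimate the cohort trace totals.
microsim_totals <- function(spec, arm, n = 20000, seed = 1) {
  set.seed(seed)
  n_cycles <- spec$horizon / spec$cycle_length
  costs <- dplyr::arrange(dplyr::filter(spec$costs, group == arm), cycle)
  trans <- dplyr::arrange(dplyr::filter(spec$transitions, group == arm), cycle)
  cost_vec <- costs$cost_per_nonrecovered[match(seq_len(n_cycles), costs$cycle)]
  u_protocol <- if (arm == "index") spec$utilities$u_index_protocol else
    spec$utilities$u_control_protocol
  u_r <- spec$utilities$u_recovered
  u_n <- spec$utilities$u_non_recovered
  ypc <- spec$cycle_length / 12

  nonrec <- rep(TRUE, n)
  qaly <- cost <- qaly_d <- cost_d <- numeric(n)
  for (k in seq_len(n_cycles)) {
    d <- discount_factor(k, spec)
    u_k <- if (k == 1) rep(u_protocol, n) else ifelse(nonrec, u_n, u_r)
    q_inc <- u_k * ypc
    c_inc <- ifelse(nonrec, cost_vec[k], 0)
    if (k == 1) c_inc <- rep(cost_vec[1], n)
    qaly <- qaly + q_inc; cost <- cost + c_inc
    qaly_d <- qaly_d + q_inc * d; cost_d <- cost_d + c_inc * d
    if (k < n_cycles) {
      p_rec <- trans$p_recover[match(k, trans$cycle)]
      p_rel <- trans$p_relapse[match(k, trans$cycle)]
      roll <- runif(n)
      nonrec <- ifelse(nonrec, roll >= p_rec, roll < p_rel)
    }
  }
  list(qaly = mean(qaly), cost = mean(cost),
       qaly_disc = mean(qaly_d), cost_disc = mean(cost_d),
       se_qaly = sd(qaly) / sqrt(n), se_cost = sd(cost) / sqrt(n))
}
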