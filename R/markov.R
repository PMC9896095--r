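#' Specify the two-state Markov cohort model
#'
#' Bundles the model inputs: the utility set, the per-cycle cost schedule,
#' the per-cycle transition schedule, the time grid and the discounting
#' settings. The model has two live states (recovered / non-recovered), a
#' closed cohort (no death state over the 8-year working-age horizon), a
#' 3-month cycle and a 96-month horizon by default, and discounts costs and
#' effects at an annual 3% rate.
#'
#' @param utilities a `utility_set` (see [model_utilities()]).
#' @param costs a `cost_schedule`.
#' @param transitions a `transition_schedule`.
#' @param cycle_length months per cycle (default 3).
#' @param horizon months (default 96); must be a multiple of `cycle_length`.
#' @param discount_rate annual rate in \[0, 1) (default 0.03).
#' @param discounting logical; `FALSE` gives undiscounted accrual only.
#' @param half_cycle_correction logical; if `TRUE`, accrual uses trapezoidal
#'   occupancy (the mean of the state fractions entering and leaving each
#'   cycle). Default `FALSE`: full-cycle occupancy with mid-cycle
#'   discounting.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(utilities, costs, transitions, cycle_length = 3,
                       horizon = 96, discount_rate = 0.03, discounting = TRUE,
                       half_cycle_correction = FALSE) {
  stopifnot(inherits(utilities, "utility_set"))
  if (horizon %% cycle_length != 0) {
    abort("horizon must be a multiple of cycle_length")
  }
  if (discount_rate < 0 || discount_rate >= 1) {
    abort("discount_rate must lie in [0, 1)")
  }
  structure(
    list(
      utilities = utilities, costs = as_tibble(costs),
      transitions = as_tibble(transitions),
      cycle_length = cycle_length, horizon = horizon,
      discount_rate = discount_rate, discounting = discounting,
      half_cycle_correction = half_cycle_correction
    ),
    class = "model_spec"
  )
}

#' Discount factor for a model cycle
#'
#' Present-value factor \eqn{(1 + r)^{-t}} with \eqn{t} the cycle midpoint in
#' years. With `discounting = FALSE` or a zero rate the factor is 1.
#'
#' @param cycle_index cycle number(s), starting at 1.
#' @param spec a `model_spec`.
#' @return numeric vector of factors in (0, 1\].
#' @export
discount_factor <- function(cycle_index, spec) {
  stopifnot(all(cycle_index >= 1))
  if (!spec$discounting || spec$discount_rate == 0) {
    return(rep(1, length(cycle_index)))
  }
  t_years <- ((cycle_index - 1) * spec$cycle_length + spec$cycle_length / 2) / 12
  (1 + spec$discount_rate)^(-t_years)
}

#' Run the cohort model for one arm
#'
#' Simulates the closed cohort over the horizon. The cohort starts 100%
#' non-recovered; during the first (per-protocol) cycle everyone carries the
#' arm-specific protocol utility and the arm's mean cost per participant;
#' from the second cycle onward the pooled recovered / non-recovered
#' utilities apply, the per-cycle cost applies to the non-recovered fraction,
#' and the state update between cycles is
#' \deqn{f_N' = f_N (1 - p_{recover}) + f_R \, p_{relapse}.}
#' QALYs accrue as area under the utility-time curve:
#' per-cycle increment \eqn{(f_R u_R + f_N u_N) \times cycle/12}, discounted
#' at the cycle midpoint.
#'
#' @param spec a `model_spec`.
#' @param arm `"index"` or `"control"`.
#' @return a `cohort_trace` tibble, one row per cycle, with state fractions,
#'   per-cycle and cumulative QALYs and costs, discounted and undiscounted.
#' @export
run_cohort <- function(spec, arm = c("index", "control")) {
  stopifnot(inherits(spec, "model_spec"))
  arm <- match.arg(arm)
  n_cycles <- spec$horizon / spec$cycle_length

  costs <- spec$costs %>% filter(.data$group == arm) %>% arrange(.data$cycle)
  trans <- spec$transitions %>% filter(.data$group == arm) %>% arrange(.data$cycle)
  missing_cost <- setdiff(seq_len(n_cycles), costs$cycle)
  if (length(missing_cost) > 0) {
    abort(sprintf("cost schedule missing cycle %s for arm '%s'",
                  missing_cost[1], arm))
  }
  missing_tr <- setdiff(seq_len(n_cycles - 1), trans$cycle)
  if (length(missing_tr) > 0) {
    abort(sprintf("transition schedule missing cycle %s for arm '%s'",
                  missing_tr[1], arm))
  }
  cost_vec <- costs$cost_per_nonrecovered[match(seq_len(n_cycles), costs$cycle)]
  p_rec <- trans$p_recover[match(seq_len(n_cycles - 1), trans$cycle)]
  p_rel <- trans$p_relapse[match(seq_len(n_cycles - 1), trans$cycle)]

  u_protocol <- if (arm == "index") spec$utilities$u_index_protocol else
    spec$utilities$u_control_protocol
  u_r <- spec$utilities$u_recovered
  u_n <- spec$utilities$u_non_recovered

  # state fractions *during* each cycle, plus the post-horizon state for the
  # optional trapezoidal correction
  f_n <- numeric(n_cycles + 1)
  f_n[1] <- 1
  for (k in seq_len(n_cycles)) {
    p_r_k <- if (k <= n_cycles - 1) p_rec[k] else 0
    p_l_k <- if (k <= n_cycles - 1) p_rel[k] else 0
    f_n[k + 1] <- f_n[k] * (1 - p_r_k) + (1 - f_n[k]) * p_l_k
  }
  occ_n <- if (spec$half_cycle_correction) {
    (f_n[seq_len(n_cycles)] + f_n[seq_len(n_cycles) + 1]) / 2
  } else {
    f_n[seq_len(n_cycles)]
  }
  occ_r <- 1 - occ_n

  cyc <- seq_len(n_cycles)
  years_per_cycle <- spec$cycle_length / 12
  mean_u <- ifelse(cyc == 1, u_protocol, occ_r * u_r + occ_n * u_n)
  qaly <- mean_u * years_per_cycle
  cost <- occ_n * cost_vec
  # cycle 1 costs are per participant: the whole cohort is non-recovered
  cost[1] <- cost_vec[1] * f_n[1]
  disc <- discount_factor(cyc, spec)

  trace <- tibble(
    cycle = cyc,
    month_start = (cyc - 1) * spec$cycle_length,
    month_end = cyc * spec$cycle_length,
    fraction_recovered = 1 - f_n[cyc],
    fraction_non_recovered = f_n[cyc],
    mean_utility = mean_u,
    qaly = qaly,
    cost = cost,
    discount = disc,
    qaly_disc = qaly * disc,
    cost_disc = cost * disc,
    cum_qaly = cumsum(qaly),
    cum_cost = cumsum(cost),
    cum_qaly_disc = cumsum(qaly * disc),
    cum_cost_disc = cumsum(cost * disc)
  )
  structure(trace, arm = arm, cycle_length = spec$cycle_length,
            discount_rate = spec$discount_rate,
            discounting = spec$discounting,
            class = c("cohort_trace", class(trace)))
}

#' Model-predicted recovery curve
#'
#' Extracts the percentage of the cohort recovered at given months (the
#' state fraction during the cycle ending at each month), for comparison
#' with the observed follow-up proportions.
#'
#' @param trace a `cohort_trace`.
#' @param months months at which to read the curve; defaults to the
#'   follow-up grid intersected with the trace.
#' @return tibble with columns `month`, `percent_recovered`.
#' @export
predicted_recovery_curve <- function(trace, months = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(months)) {
    months <- intersect(FOLLOW_UP_MONTHS, trace$month_end)
  }
  idx <- match(months, trace$month_end)
  if (any(is.na(idx))) {
    abort(sprintf("month %s is not a cycle end of this trace",
                  months[which(is.na(idx))[1]]))
  }
  tibble(month = months,
         percent_recovered = 100 * trace$fraction_recovered[idx])
}
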