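#' Incremental cost-effectiveness analysis of two arm traces
#'
#' Computes the incremental QALYs (index minus control, baseline-adjusted),
#' incremental costs, and either the ICER or a dominance verdict, discounted
#' and undiscounted. Because the two arms differed in mean utility at the
#' original baseline examination, the QALY difference is adjusted by
#' difference-in-differences: the baseline utility gap times the horizon in
#' years is subtracted (times the discounted year total for the discounted
#' endpoint). With equal or unspecified baselines the adjustment vanishes.
#'
#' @param trace_index,trace_control `cohort_trace` objects for the two arms,
#'   sharing cycle grid and discounting settings.
#' @param baseline_utilities named numeric vector `c(index = , control = )`
#'   of baseline SF-6D utilities, or `NULL` for no adjustment.
#' @return an `econ_result`: list with `delta_qaly`, `delta_cost_sek`,
#'   `icer`, `verdict` and their `_disc` counterparts.
#' @export
incremental_analysis <- function(trace_index, trace_control,
                                 baseline_utilities = NULL) {
  stopifnot(inherits(trace_index, "cohort_trace"),
            inherits(trace_control, "cohort_trace"))
  if (nrow(trace_index) != nrow(trace_control) ||
      !isTRUE(all.equal(trace_index$month_end, trace_control$month_end))) {
    abort("traces must share the same cycle grid")
  }
  if (!identical(attr(trace_index, "discount_rate"),
                 attr(trace_control, "discount_rate")) ||
      !identical(attr(trace_index, "discounting"),
                 attr(trace_control, "discounting"))) {
    abort("traces must share discounting settings")
  }

  cl <- attr(trace_index, "cycle_length")
  horizon_years <- max(trace_index$month_end) / 12
  disc_years <- sum(trace_index$discount) * cl / 12

  adj <- 0
  if (!is.null(baseline_utilities)) {
    stopifnot(all(c("index", "control") %in% names(baseline_utilities)))
    adj <- baseline_utilities[["index"]] - baseline_utilities[["control"]]
  }

  last <- nrow(trace_index)
  dq <- (trace_index$cum_qaly[last] - trace_control$cum_qaly[last]) -
    adj * horizon_years
  dc <- trace_index$cum_cost[last] - trace_control$cum_cost[last]
  dq_d <- (trace_index$cum_qaly_disc[last] - trace_control$cum_qaly_disc[last]) -
    adj * disc_years
  dc_d <- trace_index$cum_cost_disc[last] - trace_control$cum_cost_disc[last]

  verdict_of <- function(dq, dc) {
    if (dq > 0 && dc < 0) "dominant"
    else if (dq < 0 && dc > 0) "dominated"
    else if (dq == 0 && dc == 0) "equivalent"
    else if (dq == 0) "undefined"
    else "icer"
  }
  icer_of <- function(dq, dc) if (dq != 0) dc / dq else NA_real_

  structure(
    list(
      delta_qaly = dq, delta_cost_sek = dc,
      icer = icer_of(dq, dc), verdict = verdict_of(dq, dc),
      delta_qaly_disc = dq_d, delta_cost_sek_disc = dc_d,
      icer_disc = icer_of(dq_d, dc_d), verdict_disc = verdict_of(dq_d, dc_d)
    ),
    class = "econ_result"
  )
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result>\n",
      sprintf("  undiscounted: dQALY %+0.4f, dCost %+0.0f SEK -> %s%s\n",
              x$delta_qaly, x$delta_cost_sek, x$verdict,
              if (x$verdict == "icer") sprintf(" (%0.0f SEK/QALY)", x$icer) else ""),
      sprintf("  discounted:   dQALY %+0.4f, dCost %+0.0f SEK -> %s%s\n",
              x$delta_qaly_disc, x$delta_cost_sek_disc, x$verdict_disc,
              if (x$verdict_disc == "icer") sprintf(" (%0.0f SEK/QALY)", x$icer_disc) else ""),
      sep = "")
  invisible(x)
}

#' Per-participant total cost over the records
#'
#' @param records a validated `fu_records` tibble.
#' @return tibble with `participant_id`, `group`, `total_cost_sek`.
#' @export
participant_cost_totals <- function(records) {
  records <- validate_records(records)
  records %>%
    group_by(.data$participant_id, .data$group) %>%
    summarise(total_cost_sek = sum(.data$cost_sek), .groups = "drop")
}

#' Mean cost per participant with a bootstrap confidence interval
#'
#' Arithmetic mean of the individual 96-month cost totals in one arm, with a
#' seeded nonparametric percentile bootstrap interval (costs are right-skewed
#' so the interval is typically asymmetric).
#'
#' @param records a validated `fu_records` tibble.
#' @param arm `"index"` or `"control"`.
#' @param denominator divisor for the mean; defaults to the number of
#'   participants with records in the arm.
#' @param conf_level confidence level (default 0.95).
#' @param boot_reps bootstrap resamples (default 10000).
#' @param seed RNG seed for the bootstrap; `NULL` leaves the RNG state alone.
#' @return list with `mean_sek`, `ci`, `n`, `denominator`, `totals`.
#' @export
mean_cost_per_participant <- function(records, arm, denominator = NULL,
                                      conf_level = 0.95, boot_reps = 10000,
                                      seed = NULL) {
  totals <- participant_cost_totals(records) %>% filter(.data$group == arm)
  if (nrow(totals) == 0) abort(sprintf("no participants in arm '%s'", arm))
  x <- totals$total_cost_sek
  n <- length(x)
  if (is.null(denominator)) denominator <- n
  if (denominator <= 0) abort("denominator must be positive")
  mean_sek <- sum(x) / denominator

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  boot_means <- vapply(
    seq_len(boot_reps),
    function(i) sum(x[sample.int(n, n, replace = TRUE)]) / denominator,
    numeric(1)
  )
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot_means, c(alpha / 2, 1 - alpha / 2), type = 7))
  list(mean_sek = mean_sek, ci = ci, n = n, denominator = denominator,
       totals = totals)
}

#' Validate the model against observed recovery
#'
#' Compares the model-predicted percentage of recovered patients with the
#' observed follow-up proportions, per follow-up month, and returns a
#' verdict: the model is valid iff the largest absolute percentage-point
#' difference does not exceed the tolerance.
#'
#' @param predicted tibble with `month`, `percent_recovered` (see
#'   [predicted_recovery_curve()]).
#' @param observed tibble with `month`, `percent_recovered` (see
#'   [observed_recovery()]).
#' @param tolerance_pct maximum tolerated absolute difference in percentage
#'   points (default 5).
#' @return list with `table` (month, predicted, observed, abs_diff),
#'   `max_abs_diff` and logical `valid`.
#' @export
validate_model <- function(predicted, observed, tolerance_pct = 5) {
  if (!setequal(predicted$month, observed$month)) {
    abort("mismatched follow-up grids between predicted and observed")
  }
  tab <- tibble(month = sort(predicted$month)) %>%
    mutate(
      predicted = predicted$percent_recovered[match(.data$month, predicted$month)],
      observed = observed$percent_recovered[match(.data$month, observed$month)],
      abs_diff = abs(.data$predicted - .data$observed)
    )
  list(table = tab, max_abs_diff = max(tab$abs_diff),
       valid = max(tab$abs_diff) <= tolerance_pct)
}

#' Two-standard-deviation cost outlier sensitivity analysis
#'
#' Pools the individual 96-month cost totals of both arms, computes their
#' mean and (sample) standard deviation, removes individuals whose total
#' exceeds mean + 2 SD, and recomputes the arm means and bootstrap
#' confidence intervals. Exclusion is one-sided: only high-cost individuals
#' are ever removed, so the after-exclusion mean cannot exceed the before
#' mean. With no individual over the threshold the primary result is
#' reproduced exactly.
#'
#' @param records a validated `fu_records` tibble covering both arms.
#' @param conf_level,boot_reps,seed bootstrap settings passed to
#'   [mean_cost_per_participant()].
#' @return a `sensitivity_result`: list with `excluded_ids`, `threshold_sek`,
#'   `pooled_mean_sek`, `pooled_sd_sek`, and `before` / `after` tibbles of
#'   per-arm means and intervals.
#' @export
sensitivity_two_sd <- function(records, conf_level = 0.95, boot_reps = 10000,
                               seed = NULL) {
  totals <- participant_cost_totals(records)
  if (nrow(totals) < 3) abort("need at least 3 individuals with cost totals")
  m <- mean(totals$total_cost_sek)
  s <- sd(totals$total_cost_sek)
  if (s == 0) {
    warning("degenerate cost distribution (SD = 0): no exclusions")
    excluded <- character(0)
  } else {
    excluded <- totals$participant_id[totals$total_cost_sek > m + 2 * s]
  }
  kept <- records[!records$participant_id %in% excluded, ]

  arm_summary <- function(recs) {
    bind_rows(lapply(sort(unique(totals$group)), function(arm) {
      res <- mean_cost_per_participant(recs, arm, conf_level = conf_level,
                                       boot_reps = boot_reps, seed = seed)
      tibble(group = arm, mean_sek = res$mean_sek,
             ci_lo = res$ci[1], ci_hi = res$ci[2], n = res$n)
    }))
  }
  structure(
    list(
      excluded_ids = excluded,
      threshold_sek = m + 2 * s,
      pooled_mean_sek = m, pooled_sd_sek = s,
      before = arm_summary(records),
      after = arm_summary(kept)
    ),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> threshold ", round(x$threshold_sek), " SEK; excluded: ",
      if (length(x$excluded_ids) == 0) "none" else paste(x$excluded_ids, collapse = ", "),
      "\n", sep = "")
  cat("before:\n"); print(x$before)
  cat("after:\n"); print(x$after)
  invisible(x)
}
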