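#' Default pipeline configuration
#'
#' @param mode input mode: `"fixtures"` (packaged aggregate tables),
#'   `"panel"` (a follow-up CSV), or `"simulate"` (synthetic trial).
#' @param ... overrides for any configuration field; see Details.
#'
#' @details Fields: `mode`; `panel_path` (panel mode); `sim` (list of
#'   [sim_config()] arguments, simulate mode); `discount_rate` (0.03);
#'   `cycle_length` (3); `horizon` (96); `discounting` (TRUE);
#'   `half_cycle_correction` (FALSE); `transition_method` (`"net"`);
#'   `validation_tolerance_pct` (5); `bootstrap_reps` (10000); `seed` (1);
#'   `baseline_utilities` (named list/vector or NULL); `output_dir`.
#'
#' @return a named list of configuration values.
#' @export
pipeline_config <- function(mode = c("fixtures", "panel", "simulate"), ...) {
  cfg <- list(
    mode = match.arg(mode),
    panel_path = NULL,
    sim = list(),
    discount_rate = 0.03,
    cycle_length = 3,
    horizon = 96,
    discounting = TRUE,
    half_cycle_correction = FALSE,
    transition_method = "net",
    validation_tolerance_pct = 5,
    bootstrap_reps = 10000,
    seed = 1L,
    baseline_utilities = NULL,
    output_dir = tempfile("mtcea-run-")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$mode)) abort(sprintf("%s: field 'mode' is required", basename(path)))
  do.call(pipeline_config, c(list(mode = raw$mode), raw[setdiff(names(raw), "mode")]))
}

#' Run the full cost-effectiveness pipeline
#'
#' Wires the stages together: input ingestion (packaged tables, a follow-up
#' panel CSV, or a simulated trial), state classification and panel building,
#' estimation of utilities, cost and transition schedules, the Markov cohort
#' run for both arms, incremental analysis, model validation against observed
#' recovery, the 2-SD cost sensitivity analysis (when individual records are
#' available), and artefact emission: CSV/JSON outputs plus a Markdown report
#' and a log of every estimated quantity. Deterministic for a fixed
#' configuration and seed.
#'
#' @param config a configuration list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML config file.
#' @return (invisibly) a list with all intermediate and final objects and
#'   the output directory.
#' @export
run_pipeline <- function(config = pipeline_config("fixtures")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # --- inputs ---------------------------------------------------------------
  records <- NULL
  reported <- NULL
  if (config$mode == "fixtures") {
    fix <- table_fixtures()
    panel <- fix$panel
    reported <- fix$reported
    costs <- cost_schedule_from_totals(fix$costs, panel,
                                       cycle_length = config$cycle_length,
                                       horizon = config$horizon)
    cost_summary <- summarise_cost_table(fix$costs)
    log_add("inputs: packaged aggregate tables (utility panel + cost totals)")
  } else {
    if (config$mode == "panel") {
      records <- read_panel_csv(config$panel_path)
      log_add("inputs: follow-up panel %s (%d records)", config$panel_path,
              nrow(records))
    } else {
      sim <- simulate_trial(do.call(sim_config, config$sim))
      records <- sim$records
      write_panel_csv(records, file.path(config$output_dir, "panel_records.csv"))
      log_add("inputs: simulated trial, seed %d (%d records)",
              sim$truth$config$seed, nrow(records))
    }
    panel <- build_state_panel(records)
    costs <- estimate_cost_schedule(records, panel,
                                    cycle_length = config$cycle_length,
                                    horizon = config$horizon)
    cost_summary <- NULL
  }

  # --- estimation -----------------------------------------------------------
  utilities <- model_utilities(panel)
  log_add("utilities: protocol index %.3f / control %.3f; pooled recovered %.3f / non-recovered %.3f",
          utilities$u_index_protocol, utilities$u_control_protocol,
          utilities$u_recovered, utilities$u_non_recovered)
  transitions <- estimate_transitions(panel, cycle_length = config$cycle_length,
                                      horizon = config$horizon,
                                      method = config$transition_method)
  spans <- attr(transitions, "spans")
  for (k in seq_len(nrow(spans))) {
    log_add("transitions (%s, %d-%d months): p_recover %.4f, p_relapse %.4f [%s]",
            spans$group[k], spans$from_month[k], spans$to_month[k],
            spans$p_recover[k], spans$p_relapse[k], config$transition_method)
  }

  spec <- model_spec(utilities, costs, transitions,
                     cycle_length = config$cycle_length, horizon = config$horizon,
                     discount_rate = config$discount_rate,
                     discounting = config$discounting,
                     half_cycle_correction = config$half_cycle_correction)

  # --- cohort model ---------------------------------------------------------
  traces <- lapply(setNames(ARMS, ARMS), function(arm) run_cohort(spec, arm))
  for (arm in ARMS) {
    tr <- traces[[arm]]
    log_add("cohort %s: QALY %.4f (disc %.4f), cost %.0f SEK (disc %.0f)",
            arm, max(tr$cum_qaly), max(tr$cum_qaly_disc),
            max(tr$cum_cost), max(tr$cum_cost_disc))
  }

  baselines <- config$baseline_utilities
  if (!is.null(baselines)) baselines <- unlist(baselines)
  econ <- incremental_analysis(traces$index, traces$control,
                               baseline_utilities = baselines)
  log_add("incremental: dQALY %.4f (disc %.4f), dCost %.0f SEK (disc %.0f), verdict %s",
          econ$delta_qaly, econ$delta_qaly_disc,
          econ$delta_cost_sek, econ$delta_cost_sek_disc, econ$verdict)

  # --- validation -----------------------------------------------------------
  validation <- lapply(setNames(ARMS, ARMS), function(arm) {
    v <- validate_model(predicted_recovery_curve(traces[[arm]]),
                        observed_recovery(panel, arm),
                        tolerance_pct = config$validation_tolerance_pct)
    log_add("validation %s: max |predicted - observed| %.2f points -> %s",
            arm, v$max_abs_diff, if (v$valid) "valid" else "invalid")
    v
  })

  # --- costs per participant & sensitivity ----------------------------------
  sensitivity <- NULL
  mean_costs <- NULL
  if (!is.null(records)) {
    mean_costs <- bind_rows(lapply(ARMS, function(arm) {
      res <- mean_cost_per_participant(records, arm,
                                       boot_reps = config$bootstrap_reps,
                                       seed = config$seed)
      tibble(group = arm, mean_sek = res$mean_sek,
             ci_lo = res$ci[1], ci_hi = res$ci[2], n = res$n)
    }))
    sensitivity <- sensitivity_two_sd(records,
                                      boot_reps = config$bootstrap_reps,
                                      seed = config$seed)
    log_add("sensitivity (2 SD): threshold %.0f SEK, excluded %d individual(s)",
            sensitivity$threshold_sek, length(sensitivity$excluded_ids))
  } else if (!is.null(cost_summary)) {
    mean_costs <- cost_summary %>%
      mutate(ci_lo = NA_real_, ci_hi = NA_real_, n = .data$denominator) %>%
      select("group", "mean_sek", "ci_lo", "ci_hi", "n")
    log_add("mean costs from aggregate totals; no individual data, 2-SD sensitivity skipped")
  }

  # --- artefacts ------------------------------------------------------------
  out <- config$output_dir
  readr::write_csv(panel$cells, file.path(out, "state_panel.csv"))
  readr::write_csv(as_tibble(transitions), file.path(out, "transitions.csv"))
  readr::write_csv(as_tibble(costs), file.path(out, "cost_schedule.csv"))
  for (arm in ARMS) {
    readr::write_csv(as_tibble(traces[[arm]]),
                     file.path(out, sprintf("trace_%s.csv", arm)))
  }
  jsonlite::write_json(unclass(econ), file.path(out, "econ_result.json"),
                       auto_unbox = TRUE, digits = NA)
  val_tab <- bind_rows(lapply(ARMS, function(arm) {
    validation[[arm]]$table %>% mutate(group = arm, .before = 1)
  }))
  readr::write_csv(val_tab, file.path(out, "validation.csv"))
  if (!is.null(mean_costs)) {
    readr::write_csv(mean_costs, file.path(out, "mean_costs.csv"))
  }
  if (!is.null(sensitivity)) {
    jsonlite::write_json(
      list(
        excluded_ids = sensitivity$excluded_ids,
        threshold_sek = sensitivity$threshold_sek,
        pooled_mean_sek = sensitivity$pooled_mean_sek,
        pooled_sd_sek = sensitivity$pooled_sd_sek,
        before = sensitivity$before, after = sensitivity$after
      ),
      file.path(out, "sensitivity.json"), auto_unbox = TRUE, digits = NA
    )
  }
  writeLines(log_lines, file.path(out, "run_log.txt"))

  report <- render_report(config, utilities, panel, econ, validation,
                          mean_costs, sensitivity, reported)
  writeLines(report, file.path(out, "report.md"))

  invisible(list(
    config = config, panel = panel, utilities = utilities,
    transitions = transitions, costs = costs, spec = spec, traces = traces,
    econ = econ, validation = validation, mean_costs = mean_costs,
    sensitivity = sensitivity, records = records, reported = reported,
    output_dir = out, log = log_lines
  ))
}

render_report <- function(config, utilities, panel, econ, validation,
                          mean_costs, sensitivity, reported) {
  fmt_pct <- function(x) sprintf("%.1f", x)
  lines <- c(
    "# Cost-effectiveness analysis: specialised manual therapy vs orthopaedic care",
    "",
    sprintf("Input mode: `%s`; cycle %d months; horizon %d months; discount rate %.1f%%.",
            config$mode, config$cycle_length, config$horizon,
            100 * config$discount_rate),
    "",
    "## Model utilities",
    "",
    "| Quantity | Value |",
    "|---|---|",
    sprintf("| Per-protocol utility, index | %.3f |", utilities$u_index_protocol),
    sprintf("| Per-protocol utility, control | %.3f |", utilities$u_control_protocol),
    sprintf("| Pooled utility, recovered (4-96 months) | %.3f |", utilities$u_recovered),
    sprintf("| Pooled utility, non-recovered (4-96 months) | %.3f |", utilities$u_non_recovered),
    "",
    "## Incremental results (index minus control)",
    "",
    "| Endpoint | Undiscounted | Discounted |",
    "|---|---|---|",
    sprintf("| QALY gain | %.4f | %.4f |", econ$delta_qaly, econ$delta_qaly_disc),
    sprintf("| Cost difference (SEK) | %.0f | %.0f |",
            econ$delta_cost_sek, econ$delta_cost_sek_disc),
    sprintf("| Verdict | %s | %s |", econ$verdict, econ$verdict_disc),
    ""
  )
  lines <- c(lines, "## Validation: observed vs model-predicted recovery (%)", "",
             "| Arm | Month | Observed | Predicted | |diff| |", "|---|---|---|---|---|")
  for (arm in names(validation)) {
    tab <- validation[[arm]]$table
    for (k in seq_len(nrow(tab))) {
      lines <- c(lines, sprintf("| %s | %d | %s | %s | %s |", arm, tab$month[k],
                                fmt_pct(tab$observed[k]), fmt_pct(tab$predicted[k]),
                                fmt_pct(tab$abs_diff[k])))
    }
    lines <- c(lines, sprintf("| %s | verdict | | | %s |", arm,
                              if (validation[[arm]]$valid) "valid" else "invalid"))
  }
  if (!is.null(mean_costs)) {
    lines <- c(lines, "", "## Mean cost per participant (0-96 months)", "",
               "| Arm | Mean (SEK) | 95% CI | n |", "|---|---|---|---|")
    for (k in seq_len(nrow(mean_costs))) {
      ci <- if (is.na(mean_costs$ci_lo[k])) "-" else
        sprintf("%.0f - %.0f", mean_costs$ci_lo[k], mean_costs$ci_hi[k])
      lines <- c(lines, sprintf("| %s | %.0f | %s | %d |", mean_costs$group[k],
                                mean_costs$mean_sek[k], ci, mean_costs$n[k]))
    }
  }
  if (!is.null(sensitivity)) {
    lines <- c(lines, "", "## Sensitivity analysis (2-SD cost outlier exclusion)", "",
               sprintf("Pooled mean %.0f SEK, SD %.0f SEK, threshold %.0f SEK; excluded: %s.",
                       sensitivity$pooled_mean_sek, sensitivity$pooled_sd_sek,
                       sensitivity$threshold_sek,
                       if (length(sensitivity$excluded_ids) == 0) "none" else
                         paste(sensitivity$excluded_ids, collapse = ", ")),
               "", "| Arm | Mean before (SEK) | Mean after (SEK) |", "|---|---|---|")
    for (k in seq_len(nrow(sensitivity$before))) {
      lines <- c(lines, sprintf("| %s | %.0f | %.0f |",
                                sensitivity$before$group[k],
                                sensitivity$before$mean_sek[k],
                                sensitivity$after$mean_sek[k]))
    }
  }
  if (!is.null(reported)) {
    lines <- c(lines, "", "## Reported reference values (side by side)", "",
               "| Quantity | Reported |", "|---|---|")
    for (q in names(reported)) {
      lines <- c(lines, sprintf("| %s | %g |", q, reported[[q]]))
    }
  }
  lines
}

#' Plot observed versus model-predicted recovery
#'
#' @param validation the `validation` element of a [run_pipeline()] result
#'   (per-arm list of validation tables).
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_validation <- function(validation) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_validation() requires the ggplot2 package")
  }
  tab <- bind_rows(lapply(names(validation), function(arm) {
    validation[[arm]]$table %>% mutate(group = arm)
  })) %>%
    tidyr::pivot_longer(c("predicted", "observed"),
                        names_to = "source", values_to = "percent")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$month, y = .data$percent,
                                    colour = .data$group,
                                    linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Month", y = "Recovered (%)",
                  title = "Model validation: observed vs predicted recovery") +
    ggplot2::theme_minimal()
}
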