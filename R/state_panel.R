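#' Construct a state panel
#'
#' A state panel is the in-memory form of the trial's aggregate follow-up
#' table: for every (group, follow-up month, category) cell it stores the
#' participant count and mean SF-6D utility. Categories are the treated
#' intervention types plus `recovered_no_treatment` and
#' `not_recovered_no_treatment` (untreated but still symptomatic, counted as
#' recovered for costing under the health-care perspective).
#'
#' @param cells tibble with columns `group`, `follow_up`, `category`, `count`,
#'   `mean_utility`.
#' @param states optional per-participant state table (columns
#'   `participant_id`, `group`, `follow_up`, `cost_state`, `utility_state`),
#'   retained when the panel is built from individual records; enables exact
#'   transition-flow estimation.
#' @return an object of class `state_panel`.
#' @export
state_panel <- function(cells, states = NULL) {
  cells <- as_tibble(cells)
  stopifnot(all(c("group", "follow_up", "category", "count", "mean_utility")
                %in% names(cells)))
  if (any(cells$count < 0)) abort("cell counts must be non-negative")
  u <- cells$mean_utility
  if (any(!is.na(u) & (u < 0 | u > 1))) abort("mean utilities must lie in [0, 1]")
  bad <- !cells$category %in% c(TREATED_CATEGORIES, NO_TREATMENT_CATEGORIES)
  if (any(bad)) {
    abort(sprintf("unknown panel category '%s'", cells$category[which(bad)[1]]))
  }
  enrolled <- cells %>%
    group_by(.data$group, .data$follow_up) %>%
    summarise(n = sum(.data$count), .groups = "drop")
  structure(
    list(cells = cells, enrolled = enrolled, states = states),
    class = "state_panel"
  )
}

#' @export
print.state_panel <- function(x, ...) {
  cat("<state_panel> ", nrow(x$cells), " cells, follow-ups at ",
      paste(sort(unique(x$cells$follow_up)), collapse = ", "), " months\n",
      sep = "")
  print(x$enrolled, n = Inf)
  invisible(x)
}

#' Build a state panel from follow-up records
#'
#' Tallies participants per (group, follow-up, category) and averages their
#' measured utilities. A treated participant's category is the intervention
#' with the highest cost in the window (ties broken by the canonical category
#' order, mirroring how the trial assigned each participant a single column);
#' untreated participants fall into `recovered_no_treatment` or
#' `not_recovered_no_treatment` according to their symptom flag.
#'
#' Enrolment at a follow-up is defined by the presence of records in the
#' window: participants who withdrew contribute until withdrawal and
#' denominators shrink accordingly (no imputation).
#'
#' @param records a validated `fu_records` tibble (see [validate_records()]).
#' @return a `state_panel` with per-participant states retained.
#' @export
build_state_panel <- function(records) {
  records <- validate_records(records)
  records$follow_up <- window_follow_up(records$period_end_month)

  per_part <- records %>%
    group_by(.data$participant_id, .data$group, .data$follow_up) %>%
    summarise(
      treated = any(.data$treatment_category != "none"),
      flagged = any(.data$untreated_nonrecovered_flag %in% TRUE),
      category = if (any(.data$treatment_category != "none")) {
        tr <- .data$treatment_category != "none"
        cats <- .data$treatment_category[tr]
        costs <- .data$cost_sek[tr]
        top <- costs == max(costs)
        cats[top][order(match(cats[top], TREATED_CATEGORIES))][1]
      } else if (any(.data$untreated_nonrecovered_flag %in% TRUE)) {
        "not_recovered_no_treatment"
      } else {
        "recovered_no_treatment"
      },
      utility = if (all(is.na(.data$utility))) NA_real_ else
        mean(.data$utility, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      cost_state = ifelse(.data$treated, "non_recovered", "recovered"),
      utility_state = ifelse(.data$treated | .data$flagged,
                             "non_recovered", "recovered")
    )

  cells <- per_part %>%
    group_by(.data$group, .data$follow_up, .data$category) %>%
    summarise(
      count = n(),
      mean_utility = if (all(is.na(.data$utility))) NA_real_ else
        mean(.data$utility, na.rm = TRUE),
      .groups = "drop"
    )

  states <- per_part %>%
    select("participant_id", "group", "follow_up", "cost_state", "utility_state")

  state_panel(cells, states = states)
}

#' Count-weighted mean utility
#'
#' Pools cell mean utilities weighted by cell counts:
#' \eqn{\sum u_i n_i / \sum n_i}. This is how the per-protocol group
#' utilities and the pooled recovered / non-recovered utilities are prepared
#' for the Markov model. Cells with zero count are ignored.
#'
#' @param mean_utility numeric vector of cell mean utilities.
#' @param count non-negative integer vector of cell counts.
#' @param digits decimals to round to (the trial reports 3); `NULL` for full
#'   precision.
#' @return the weighted mean utility.
#' @export
weighted_utility <- function(mean_utility, count, digits = 3) {
  stopifnot(length(mean_utility) == length(count))
  if (any(count < 0)) abort("counts must be non-negative")
  keep <- count > 0
  if (!any(keep)) abort("empty stratum: all cell counts are zero")
  out <- sum(mean_utility[keep] * count[keep]) / sum(count[keep])
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Utilities prepared for the Markov model
#'
#' Derives the four model utilities from a state panel: the arm-specific
#' per-protocol utilities (all participants at the first follow-up, weighted
#' by cell counts) and the pooled recovered / non-recovered utilities for the
#' remainder of the horizon, both arms together. Non-recovered pooling
#' includes the treated categories *and* the untreated-but-symptomatic
#' category, whose members are recovered for costing but carry non-recovered
#' quality of life.
#'
#' @param panel a `state_panel`.
#' @param protocol_follow_up the follow-up month closing the per-protocol
#'   period (default 3).
#' @param digits rounding for the reported utilities (default 3).
#' @return an object of class `utility_set`: a list with
#'   `u_index_protocol`, `u_control_protocol`, `u_recovered`,
#'   `u_non_recovered`.
#' @export
model_utilities <- function(panel, protocol_follow_up = 3, digits = 3) {
  stopifnot(inherits(panel, "state_panel"))
  cells <- panel$cells
  protocol <- function(arm) {
    x <- cells %>% filter(.data$group == arm,
                          .data$follow_up == protocol_follow_up)
    if (nrow(x) == 0) abort(sprintf("no protocol-period cells for arm '%s'", arm))
    weighted_utility(x$mean_utility, x$count, digits = digits)
  }
  post <- cells %>% filter(.data$follow_up > protocol_follow_up)
  nonrec <- post %>%
    filter(.data$category %in% c(TREATED_CATEGORIES, "not_recovered_no_treatment"))
  rec <- post %>% filter(.data$category == "recovered_no_treatment")
  structure(
    list(
      u_index_protocol = protocol("index"),
      u_control_protocol = protocol("control"),
      u_recovered = weighted_utility(rec$mean_utility, rec$count, digits = digits),
      u_non_recovered = weighted_utility(nonrec$mean_utility, nonrec$count,
                                         digits = digits)
    ),
    class = "utility_set"
  )
}

#' @export
print.utility_set <- function(x, ...) {
  cat("<utility_set>\n",
      sprintf("  per-protocol: index %.3f, control %.3f\n",
              x$u_index_protocol, x$u_control_protocol),
      sprintf("  post-protocol pooled: recovered %.3f, non-recovered %.3f\n",
              x$u_recovered, x$u_non_recovered), sep = "")
  invisible(x)
}

#' Cost-state recovery proportion at a follow-up
#'
#' Share of enrolled participants classified as recovered for costing
#' (no treatment in the window) at a given follow-up, as a percentage.
#'
#' @param panel a `state_panel`.
#' @param group `"index"` or `"control"`.
#' @param follow_up follow-up month present in the panel.
#' @param digits rounding (default 0, integer percent as reported; `NULL`
#'   for full precision).
#' @return percentage recovered.
#' @export
recovery_proportion <- function(panel, group, follow_up, digits = 0) {
  stopifnot(inherits(panel, "state_panel"))
  cells <- panel$cells %>%
    filter(.data$group == !!group, .data$follow_up == !!follow_up)
  if (nrow(cells) == 0) {
    abort(sprintf("no panel cells for group '%s' at follow-up %s",
                  group, follow_up))
  }
  rec <- sum(cells$count[cells$category %in% NO_TREATMENT_CATEGORIES])
  pct <- 100 * rec / sum(cells$count)
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

#' Observed recovery proportions across follow-ups
#'
#' @param panel a `state_panel`.
#' @param group arm label.
#' @return tibble with columns `month` and `percent_recovered` (unrounded),
#'   one row per follow-up in the panel.
#' @export
observed_recovery <- function(panel, group) {
  months <- sort(unique(panel$cells$follow_up[panel$cells$group == group]))
  tibble(
    month = months,
    percent_recovered = vapply(
      months, function(m) recovery_proportion(panel, group, m, digits = NULL),
      numeric(1)
    )
  )
}
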