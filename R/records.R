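#' Validate follow-up records
#'
#' Checks a long-format table of participant follow-up records against the
#' contract used throughout the package: one row per participant x period
#' (x treatment), columns `participant_id`, `group`, `period_start_month`,
#' `period_end_month`, `treatment_category`, `cost_sek`, `utility`,
#' `untreated_nonrecovered_flag`. Periods must be disjoint within a
#' participant and must fall inside a single follow-up window; untreated
#' periods carry zero cost; utilities, when present, lie in \[0, 1\].
#'
#' @param records a data frame of follow-up records.
#' @param source a label (e.g. a file name) used in error messages.
#' @return the records as a validated tibble, invisibly classed `fu_records`.
#' @export
validate_records <- function(records, source = "records") {
  required <- c(
    "participant_id", "group", "period_start_month", "period_end_month",
    "treatment_category", "cost_sek", "utility", "untreated_nonrecovered_flag"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s): %s", source,
                  paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)

  bad_group <- !records$group %in% ARMS
  if (any(bad_group)) {
    abort(sprintf("%s: field 'group' invalid at row(s) %s (must be one of %s)",
                  source, paste(head(which(bad_group), 5), collapse = ", "),
                  paste(ARMS, collapse = ", ")))
  }
  bad_cat <- !records$treatment_category %in% ALL_RECORD_CATEGORIES
  if (any(bad_cat)) {
    abort(sprintf(
      "%s: field 'treatment_category' unknown value '%s' at row %s",
      source, records$treatment_category[which(bad_cat)[1]], which(bad_cat)[1]
    ))
  }
  if (any(is.na(records$cost_sek) | records$cost_sek < 0)) {
    abort(sprintf("%s: field 'cost_sek' must be non-negative and non-missing", source))
  }
  untreated_cost <- records$treatment_category == "none" & records$cost_sek > 0
  if (any(untreated_cost)) {
    abort(sprintf("%s: field 'cost_sek' positive without treatment at row %s",
                  source, which(untreated_cost)[1]))
  }
  u <- records$utility
  if (any(!is.na(u) & (u < 0 | u > 1))) {
    abort(sprintf("%s: field 'utility' outside [0, 1]", source))
  }
  if (any(records$period_end_month <= records$period_start_month)) {
    abort(sprintf("%s: periods must have end > start", source))
  }

  # each period must sit inside one follow-up window
  fu_end <- window_follow_up(records$period_end_month)
  fu_prev <- c(0, FOLLOW_UP_MONTHS)[match(fu_end, FOLLOW_UP_MONTHS)]
  if (any(records$period_start_month < fu_prev)) {
    abort(sprintf("%s: period spans more than one follow-up window at row %s",
                  source, which(records$period_start_month < fu_prev)[1]))
  }

  # participants cannot be allocated to two arms
  multi_arm <- records %>%
    distinct(.data$participant_id, .data$group) %>%
    dplyr::count(.data$participant_id) %>%
    filter(.data$n > 1)
  if (nrow(multi_arm) > 0) {
    abort(sprintf("%s: participant '%s' appears in both arms",
                  source, multi_arm$participant_id[1]))
  }

  # disjoint periods per participant (rows describing distinct treatments in
  # the same window are allowed; identical periods must not conflict)
  overlap <- records %>%
    group_by(.data$participant_id) %>%
    arrange(.data$period_start_month, .by_group = TRUE) %>%
    summarise(clash = {
      dup <- duplicated(cbind(.data$period_start_month, .data$period_end_month))
      keep <- !dup
      s <- .data$period_start_month[keep]
      e <- .data$period_end_month[keep]
      any(s[-1] < e[-length(e)])
    }, .groups = "drop") %>%
    filter(.data$clash)
  if (nrow(overlap) > 0) {
    abort(sprintf("%s: participant '%s' has overlapping periods",
                  source, overlap$participant_id[1]))
  }

  class(records) <- unique(c("fu_records", class(records)))
  records
}

#' Read a follow-up panel from CSV
#'
#' Reads the delimited panel dialect written by [simulate_trial()] /
#' [write_panel_csv()] and validates it. Malformed files raise an error
#' naming the file and the offending field.
#'
#' @param path path to a CSV file.
#' @return a validated `fu_records` tibble.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel file not found: %s", path))
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      period_start_month = readr::col_double(),
      period_end_month = readr::col_double(),
      treatment_category = readr::col_character(),
      cost_sek = readr::col_double(),
      utility = readr::col_double(),
      untreated_nonrecovered_flag = readr::col_logical()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  validate_records(records, source = basename(path))
}

#' Write a follow-up panel to CSV
#'
#' @param records an `fu_records` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(records, path) {
  readr::write_csv(as_tibble(records), path, na = "")
  invisible(path)
}

#' Classify a participant-period into cost and utility states
#'
#' Under the health-care perspective, a participant is *recovered for
#' costing purposes* in a period iff no treatment was received in that period
#' (no costs are generated), regardless of symptoms. The *utility* state
#' additionally treats untreated participants who still report their disorder
#' (the `untreated_nonrecovered_flag`) as non-recovered, so that their lower
#' quality-of-life weights are pooled with the treated group.
#'
#' @param records the follow-up records of one participant in one follow-up
#'   window (possibly several treatment rows). An empty set classifies as
#'   recovered on both axes.
#' @return a list with elements `cost_state` and `utility_state`, each
#'   `"recovered"` or `"non_recovered"`.
#' @export
classify_state <- function(records) {
  if (nrow(records) == 0) {
    return(list(cost_state = "recovered", utility_state = "recovered"))
  }
  if (length(unique(records$participant_id)) > 1) {
    abort("classify_state() expects records of a single participant")
  }
  # conflicting duplicates: same period and treatment listed twice with
  # different content (cost/utility)
  conflict <- any(duplicated(records[, c("period_start_month", "period_end_month",
                                         "treatment_category")]) &
                    !duplicated(records))
  if (conflict) {
    abort(sprintf("conflicting duplicate periods for participant '%s'",
                  records$participant_id[1]))
  }
  treated <- any(records$treatment_category != "none")
  flagged <- any(records$untreated_nonrecovered_flag %in% TRUE)
  list(
    cost_state = if (treated) "non_recovered" else "recovered",
    utility_state = if (treated || flagged) "non_recovered" else "recovered"
  )
}
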