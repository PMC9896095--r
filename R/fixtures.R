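#' Packaged aggregate trial tables
#'
#' Returns the transcriptions of the trial's published aggregate tables
#' shipped with the package: the per-(group, follow-up, category) participant
#' counts and mean SF-6D utilities as a `state_panel`; the per-category cost
#' totals over the two reporting windows (baseline-12 and 13-96 months); and
#' the study's reported headline values (utilities, mean costs, recovery
#' percentages, discount rate), used as reference inputs and for
#' side-by-side reporting.
#'
#' @return list with components `panel` (a `state_panel`), `costs` (tibble:
#'   `group`, `window_start_month`, `window_end_month`, `category`,
#'   `total_cost_sek`, `n_treated`), and `reported` (named numeric vector of
#'   reported quantities).
#' @export
table_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "mtcea", mustWork = TRUE)
  cells <- readr::read_csv(path("table2_utilities.csv"),
                           show_col_types = FALSE, progress = FALSE)
  costs <- readr::read_csv(path("table3_costs.csv"),
                           show_col_types = FALSE, progress = FALSE)
  rep_tab <- readr::read_csv(path("reported_values.csv"),
                             show_col_types = FALSE, progress = FALSE)
  list(
    panel = state_panel(cells),
    costs = costs,
    reported = setNames(rep_tab$value, rep_tab$quantity)
  )
}

#' Per-arm cost summary from an aggregate cost table
#'
#' Sums a transcribed cost table over windows and categories per arm and
#' derives the mean cost per participant given each arm's denominator.
#'
#' @param cost_table tibble as in `table_fixtures()$costs`.
#' @param denominators named vector of participants per arm
#'   (default `c(index = 40, control = 38)`, the randomised arm sizes).
#' @return tibble with `group`, `total_sek`, `denominator`, `mean_sek`.
#' @export
summarise_cost_table <- function(cost_table,
                                 denominators = c(index = 40, control = 38)) {
  cost_table %>%
    group_by(.data$group) %>%
    summarise(total_sek = sum(.data$total_cost_sek, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(
      denominator = unname(denominators[.data$group]),
      mean_sek = .data$total_sek / .data$denominator
    )
}
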