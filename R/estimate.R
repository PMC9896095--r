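#' Convert a transition probability between time spans
#'
#' Constant-rate conversion of a probability observed over `from_months` to
#' an equivalent probability per `to_months`:
#' \eqn{p' = 1 - (1 - p)^{to/from}}. Keeps probabilities in \[0, 1\] and is
#' exactly consistent under compounding (converting an annual probability to
#' quarterly and compounding four quarters returns the annual probability).
#'
#' @param p probability in \[0, 1\] (vectorised).
#' @param from_months span over which `p` was observed.
#' @param to_months target span (default one 3-month cycle).
#' @return converted probability.
#' @export
prob_rescale <- function(p, from_months, to_months = 3) {
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  1 - (1 - p)^(to_months / from_months)
}

#' Estimate per-cycle transition probabilities from a state panel
#'
#' Computes, for each arm and each span between consecutive follow-ups, the
#' probability of moving non-recovered -> recovered (`p_recover`) and
#' recovered -> non-recovered (`p_relapse`), then converts each span
#' probability to a per-cycle (3-month) probability by constant-rate
#' conversion and expands it over the cycles of the span.
#'
#' Two estimation routes are available:
#' \describe{
#'   \item{`"flows"`}{uses the retained per-participant state sequences
#'     (available when the panel was built from records): newly recovered
#'     participants divided by non-recovered participants in the previous
#'     period, and vice versa, among participants observed at both
#'     follow-ups.}
#'   \item{`"net"`}{uses aggregate counts only (the only option for
#'     transcribed tables): the change in the recovered *proportion* is
#'     attributed entirely to the dominant direction, so one of the two
#'     probabilities is zero in each span. Driving the cohort engine with
#'     net-flow estimates reproduces the observed recovered fractions exactly
#'     at every follow-up.}
#' }
#'
#' @param panel a `state_panel` with at least two consecutive follow-ups.
#' @param cycle_length cycle length in months (default 3).
#' @param horizon model horizon in months (default 96).
#' @param method `"net"` (default), `"flows"`, or `"auto"` (flows when
#'   available).
#' @return a `transition_schedule`: tibble with columns `group`, `cycle`
#'   (the transition applied between cycle `t` and `t+1`, `t = 1 ...
#'   horizon/cycle_length - 1`), `p_recover`, `p_relapse`. The span-level
#'   estimates are attached as attribute `"spans"`.
#' @export
estimate_transitions <- function(panel, cycle_length = 3, horizon = 96,
                                 method = c("net", "flows", "auto")) {
  stopifnot(inherits(panel, "state_panel"))
  method <- match.arg(method)
  if (method == "auto") method <- if (!is.null(panel$states)) "flows" else "net"
  if (method == "flows" && is.null(panel$states)) {
    abort("flow estimation needs a panel built from individual records")
  }
  fus <- sort(unique(panel$cells$follow_up))
  if (length(fus) < 2) abort("panel must contain at least two consecutive follow-ups")

  span_rows <- list()
  for (arm in sort(unique(panel$cells$group))) {
    for (i in seq_len(length(fus) - 1)) {
      from <- fus[i]; to <- fus[i + 1]
      if (method == "flows") {
        st <- panel$states %>% filter(.data$group == arm)
        prev <- st %>% filter(.data$follow_up == from)
        cur <- st %>% filter(.data$follow_up == to)
        both <- inner_join(prev, cur, by = c("participant_id", "group"),
                           suffix = c("_prev", "_cur"))
        n_nr <- sum(both$cost_state_prev == "non_recovered")
        n_r <- sum(both$cost_state_prev == "recovered")
        new_rec <- sum(both$cost_state_prev == "non_recovered" &
                         both$cost_state_cur == "recovered")
        new_rel <- sum(both$cost_state_prev == "recovered" &
                         both$cost_state_cur == "non_recovered")
        if (n_nr == 0 && new_rec > 0 || n_r == 0 && new_rel > 0) {
          abort(sprintf("zero denominator with nonzero flow (%s, %s->%s months)",
                        arm, from, to))
        }
        p_rec <- if (n_nr > 0) new_rec / n_nr else 0
        p_rel <- if (n_r > 0) new_rel / n_r else 0
      } else {
        f_prev <- recovery_proportion(panel, arm, from, digits = NULL) / 100
        f_cur <- recovery_proportion(panel, arm, to, digits = NULL) / 100
        d <- f_cur - f_prev
        if (d > 0 && (1 - f_prev) <= 0) {
          abort(sprintf(
            "inconsistent cells: recovered proportion rises with no non-recovered pool (%s, %s->%s months)",
            arm, from, to))
        }
        if (d < 0 && f_prev <= 0) {
          abort(sprintf(
            "inconsistent cells: recovered proportion falls with no recovered pool (%s, %s->%s months)",
            arm, from, to))
        }
        p_rec <- if (d > 0) d / (1 - f_prev) else 0
        p_rel <- if (d < 0) -d / f_prev else 0
      }
      span_rows[[length(span_rows) + 1]] <- tibble(
        group = arm, from_month = from, to_month = to,
        span_months = to - from, p_recover = p_rec, p_relapse = p_rel
      )
    }
  }
  spans <- bind_rows(span_rows)

  n_trans <- horizon / cycle_length - 1
  sched <- spans %>%
    mutate(
      p_recover_cycle = prob_rescale(.data$p_recover, .data$span_months, cycle_length),
      p_relapse_cycle = prob_rescale(.data$p_relapse, .data$span_months, cycle_length)
    )
  out <- list()
  for (k in seq_len(nrow(sched))) {
    row <- sched[k, ]
    cycles <- seq(row$from_month / cycle_length, row$to_month / cycle_length - 1)
    out[[k]] <- tibble(
      group = row$group, cycle = cycles,
      p_recover = row$p_recover_cycle, p_relapse = row$p_relapse_cycle
    )
  }
  schedule <- bind_rows(out) %>%
    filter(.data$cycle >= 1, .data$cycle <= n_trans) %>%
    arrange(.data$group, .data$cycle)

  # spans end at the last follow-up; if the horizon extends beyond it the
  # last span's per-cycle probabilities are carried forward
  last_fu <- max(fus)
  if (last_fu / cycle_length - 1 < n_trans) {
    tail_rows <- sched %>% filter(.data$to_month == last_fu)
    extra <- lapply(seq_len(nrow(tail_rows)), function(k) {
      tibble(
        group = tail_rows$group[k],
        cycle = seq(last_fu / cycle_length, n_trans),
        p_recover = tail_rows$p_recover_cycle[k],
        p_relapse = tail_rows$p_relapse_cycle[k]
      )
    })
    schedule <- bind_rows(schedule, bind_rows(extra)) %>%
      arrange(.data$group, .data$cycle)
  }

  structure(schedule, spans = spans, class = c("transition_schedule", class(schedule)))
}

#' Estimate the per-cycle cost schedule from follow-up records
#'
#' In the model, costs for the first cycle (the per-protocol period) are the
#' mean cost per participant in each arm, since all participants count as
#' non-recovered then. Costs in later reporting windows are the window's
#' total divided by the number of cost-state non-recovered participants at
#' the window's closing follow-up, spread uniformly over the window's
#' 3-month cycles.
#'
#' @param records a validated `fu_records` tibble.
#' @param panel the `state_panel` built from the same records (supplies
#'   enrolment and non-recovered denominators).
#' @param cycle_length months per cycle (default 3).
#' @param horizon months (default 96).
#' @return a `cost_schedule`: tibble with columns `group`, `cycle`,
#'   `cost_per_nonrecovered` (SEK; the cycle-1 entry is per participant).
#' @export
estimate_cost_schedule <- function(records, panel, cycle_length = 3, horizon = 96) {
  records <- validate_records(records)
  stopifnot(inherits(panel, "state_panel"))
  records$follow_up <- window_follow_up(records$period_end_month)
  fus <- sort(unique(panel$cells$follow_up))

  out <- list()
  for (arm in sort(unique(panel$cells$group))) {
    for (i in seq_along(fus)) {
      fu <- fus[i]
      from <- if (i == 1) 0 else fus[i - 1]
      total <- sum(records$cost_sek[records$group == arm & records$follow_up == fu])
      cells <- panel$cells %>% filter(.data$group == arm, .data$follow_up == fu)
      enrolled <- sum(cells$count)
      if (i == 1) {
        denom <- enrolled
      } else {
        denom <- sum(cells$count[cells$category %in% TREATED_CATEGORIES])
      }
      if (denom == 0) {
        if (total > 0) {
          abort(sprintf(
            "undefined mean: positive cost with no non-recovered participants (%s, window ending %s months)",
            arm, fu))
        }
        per_cycle <- 0
      } else {
        n_cycles <- (fu - from) / cycle_length
        per_cycle <- total / denom / n_cycles
      }
      cycles <- seq(from / cycle_length + 1, fu / cycle_length)
      out[[length(out) + 1]] <- tibble(
        group = arm, cycle = cycles, cost_per_nonrecovered = per_cycle
      )
    }
  }
  schedule <- bind_rows(out) %>%
    filter(.data$cycle <= horizon / cycle_length) %>%
    arrange(.data$group, .data$cycle)
  structure(schedule, class = c("cost_schedule", class(schedule)))
}

#' Cost schedule from aggregate reporting-window totals
#'
#' Builds a per-cycle cost schedule from a transcribed cost table that
#' aggregates costs over coarse reporting windows (e.g. baseline-12 and
#' 13-96 months). Each window's total is allocated uniformly across its
#' 3-month cycles; the per-cycle amount is divided by the arm size for the
#' first cycle and by the panel's non-recovered count at the follow-up
#' closing the cycle's own window otherwise.
#'
#' @param cost_table tibble with columns `group`, `window_start_month`,
#'   `window_end_month`, `total_cost_sek` (category rows are summed within a
#'   window).
#' @param panel a `state_panel` supplying enrolment / non-recovered
#'   denominators at each follow-up.
#' @param cycle_length,horizon model grid (defaults 3 / 96 months).
#' @return a `cost_schedule` tibble.
#' @export
cost_schedule_from_totals <- function(cost_table, panel, cycle_length = 3,
                                      horizon = 96) {
  stopifnot(inherits(panel, "state_panel"))
  fus <- sort(unique(panel$cells$follow_up))
  windows <- cost_table %>%
    group_by(.data$group, .data$window_start_month, .data$window_end_month) %>%
    summarise(total = sum(.data$total_cost_sek, na.rm = TRUE), .groups = "drop")

  denom_at <- function(arm, cycle) {
    end_month <- cycle * cycle_length
    fu <- fus[findInterval(end_month, c(0, fus), left.open = TRUE)]
    cells <- panel$cells %>% filter(.data$group == arm, .data$follow_up == fu)
    if (cycle == 1) sum(cells$count)
    else sum(cells$count[cells$category %in% TREATED_CATEGORIES])
  }

  out <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    cycles <- seq(w$window_start_month / cycle_length + 1,
                  min(w$window_end_month, horizon) / cycle_length)
    per_cycle_total <- w$total / length(cycles)
    denoms <- vapply(cycles, function(cy) denom_at(w$group, cy), numeric(1))
    if (any(denoms == 0 & per_cycle_total > 0)) {
      abort(sprintf("undefined mean: positive cost with zero denominator (%s)",
                    w$group))
    }
    out[[k]] <- tibble(
      group = w$group, cycle = cycles,
      cost_per_nonrecovered = ifelse(denoms > 0, per_cycle_total / denoms, 0)
    )
  }
  schedule <- bind_rows(out) %>% arrange(.data$group, .data$cycle)
  structure(schedule, class = c("cost_schedule", class(schedule)))
}
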