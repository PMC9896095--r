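#' Configuration for the synthetic two-arm trial generator
#'
#' Defaults emulate the trial the analysis was designed for: 40 index
#' (specialised manual therapy) and 38 control (orthopaedic care) participants,
#' follow-ups at 3, 6, 12 and 96 months, span transition probabilities matching
#' the observed panel counts, state-dependent SF-6D utilities around the pooled
#' values, log-normal treatment costs at the magnitudes of the trial's cost
#' table, a share of untreated-but-symptomatic participants among the
#' cost-recovered, and rare dropout.
#'
#' @param n_index,n_control arm sizes (defaults 40 / 38).
#' @param transitions tibble with columns `group`, `from_month`, `to_month`,
#'   `p_recover`, `p_relapse`: the true span transition probabilities.
#' @param utilities list with `protocol_index`, `protocol_control`,
#'   `protocol_sd`, `recovered_mean`, `recovered_sd`, `non_recovered_mean`,
#'   `non_recovered_sd`. Utility draws are normal, truncated to \[0, 1\].
#' @param cost_means named vector of mean cost (SEK) per treated period, per
#'   category; draws are log-normal with `cost_sdlog` log-scale SD and the
#'   given mean.
#' @param cost_sdlog log-scale SD of the cost distribution (default 0.5).
#' @param protocol_category_probs list of per-arm named probability vectors
#'   for the treatment received during the per-protocol period.
#' @param post_category_probs list of per-arm named probability vectors for
#'   treatments of non-recovered participants after the protocol period.
#' @param p_untreated_nonrecovered probability that a cost-recovered
#'   participant still reports the disorder (default 0.25).
#' @param dropout_prob per-follow-up withdrawal probability (default 0.01).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(
    n_index = 40, n_control = 38,
    transitions = default_sim_transitions(),
    utilities = list(
      protocol_index = 0.737, protocol_control = 0.695, protocol_sd = 0.08,
      recovered_mean = 0.811, recovered_sd = 0.10,
      non_recovered_mean = 0.672, non_recovered_sd = 0.12
    ),
    cost_means = c(
      specialised_MT = 2600, physiotherapy = 13000, orthopaedics = 3000,
      surgery = 27000, orthotics = 1300, radiography_tests = 2000,
      drugs_injections = 400, paramedical = 4000
    ),
    cost_sdlog = 0.5,
    protocol_category_probs = list(
      index = c(specialised_MT = 1),
      control = c(physiotherapy = 13 / 38, orthopaedics = 20 / 38, surgery = 5 / 38)
    ),
    post_category_probs = list(
      index = c(specialised_MT = 0.15, physiotherapy = 0.25, orthopaedics = 0.25,
                surgery = 0.25, orthotics = 0.05, paramedical = 0.05),
      control = c(physiotherapy = 0.55, orthopaedics = 0.15, surgery = 0.1,
                  orthotics = 0.05, paramedical = 0.15)
    ),
    p_untreated_nonrecovered = 0.25,
    dropout_prob = 0.01,
    seed = 1L) {
  cfg <- list(
    n_index = n_index, n_control = n_control, transitions = as_tibble(transitions),
    utilities = utilities, cost_means = cost_means, cost_sdlog = cost_sdlog,
    protocol_category_probs = protocol_category_probs,
    post_category_probs = post_category_probs,
    p_untreated_nonrecovered = p_untreated_nonrecovered,
    dropout_prob = dropout_prob, seed = as.integer(seed)
  )
  if (n_index < 1 || n_control < 1) abort("cohort sizes must be >= 1")
  probs <- c(cfg$transitions$p_recover, cfg$transitions$p_relapse,
             p_untreated_nonrecovered, dropout_prob)
  if (any(probs < 0 | probs > 1) || dropout_prob >= 1) {
    abort("impossible config: probabilities must lie in [0, 1] (dropout < 1)")
  }
  if (cost_sdlog < 0 || any(unlist(utilities[grepl("_sd", names(utilities))]) < 0)) {
    abort("dispersions must be non-negative")
  }
  if (any(cost_means < 0)) abort("cost means must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Default true span transition probabilities
#'
#' Per-arm recovery / relapse probabilities over the spans between follow-ups
#' (3-6, 6-12, 12-96 months), set to the values implied by the trial's
#' observed panel counts: a faster and more sustained recovery in the index
#' arm, late relapse there, and a slower but steady recovery under standard
#' care.
#'
#' @return tibble with columns `group`, `from_month`, `to_month`,
#'   `p_recover`, `p_relapse`.
#' @export
default_sim_transitions <- function() {
  tibble(
    group = rep(c("index", "control"), each = 3),
    from_month = rep(c(3, 6, 12), 2),
    to_month = rep(c(6, 12, 96), 2),
    p_recover = c(0.72, 0.81, 0.00, 0.58, 0.17, 0.08),
    p_relapse = c(0.00, 0.00, 0.17, 0.00, 0.00, 0.00)
  )
}

rtrunc_norm01 <- function(n, mean, sd) {
  pmin(1, pmax(0, rnorm(n, mean, sd)))
}

rlnorm_mean <- function(n, mean, sdlog) {
  if (mean <= 0) return(rep(0, n))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

sample_category <- function(probs) {
  sample(names(probs), 1, prob = probs)
}

#' Simulate a two-arm trial with known ground truth
#'
#' Generates individual participant trajectories: everyone starts
#' non-recovered and is treated during the per-protocol period; states then
#' evolve between follow-ups as a two-state chain with the configured span
#' probabilities. Non-recovered participants in a window receive a treatment
#' (category drawn per arm, cost log-normal); cost-recovered participants are
#' untreated with zero cost and may still be symptomatic (utility flag).
#' Utilities are drawn truncated-normal around the state means and attached
#' to the measurement at each follow-up. Participants may withdraw before a
#' follow-up, after which they emit no records. Identical seeds give
#' identical output.
#'
#' @param config a `sim_config`.
#' @return list with `records` (an `fu_records` tibble in the panel CSV
#'   dialect) and `truth` (ground-truth ledger: per-participant states per
#'   follow-up, dropout times, and the generating config).
#' @export
simulate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fus <- FOLLOW_UP_MONTHS
  starts <- c(0, fus[-length(fus)])
  u <- config$utilities

  n <- config$n_index + config$n_control
  ids <- c(sprintf("I%04d", seq_len(config$n_index)),
           sprintf("C%04d", seq_len(config$n_control)))
  groups <- c(rep("index", config$n_index), rep("control", config$n_control))

  state <- rep("non_recovered", n)
  enrolled <- rep(TRUE, n)
  rec_chunks <- vector("list", length(fus))
  truth_chunks <- vector("list", length(fus))

  draw_categories <- function(arm_vec, probs_by_arm) {
    out <- character(length(arm_vec))
    for (arm in unique(arm_vec)) {
      sel <- arm_vec == arm
      p <- probs_by_arm[[arm]]
      out[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
    }
    out
  }

  for (w in seq_along(fus)) {
    if (w > 1) {
      enrolled <- enrolled & runif(n) >= config$dropout_prob
      # state update between follow-ups, per arm span probabilities
      p_rec <- p_rel <- numeric(n)
      for (arm in ARMS) {
        tr <- config$transitions[config$transitions$group == arm &
                                   config$transitions$from_month == fus[w - 1], ]
        if (nrow(tr) != 1) {
          abort(sprintf("config transitions missing span %s->%s for arm '%s'",
                        fus[w - 1], fus[w], arm))
        }
        p_rec[groups == arm] <- tr$p_recover
        p_rel[groups == arm] <- tr$p_relapse
      }
      roll <- runif(n)
      state <- ifelse(state == "non_recovered",
                      ifelse(roll < p_rec, "recovered", "non_recovered"),
                      ifelse(roll < p_rel, "non_recovered", "recovered"))
    }

    nonrec <- state == "non_recovered"
    category <- rep("none", n)
    if (any(nonrec)) {
      probs <- if (w == 1) config$protocol_category_probs else
        config$post_category_probs
      category[nonrec] <- draw_categories(groups[nonrec], probs)
    }
    cost <- numeric(n)
    cost[nonrec] <- rlnorm(
      sum(nonrec),
      meanlog = log(config$cost_means[category[nonrec]]) - config$cost_sdlog^2 / 2,
      sdlog = config$cost_sdlog
    )
    flagged <- rep(FALSE, n)
    flagged[!nonrec] <- runif(sum(!nonrec)) < config$p_untreated_nonrecovered

    u_mean <- ifelse(
      nonrec | flagged,
      if (w == 1) ifelse(groups == "index", u$protocol_index, u$protocol_control)
      else u$non_recovered_mean,
      u$recovered_mean
    )
    u_sd <- ifelse(nonrec | flagged,
                   if (w == 1) u$protocol_sd else u$non_recovered_sd,
                   u$recovered_sd)
    util <- rtrunc_norm01(n, u_mean, u_sd)

    rec_chunks[[w]] <- tibble(
      participant_id = ids[enrolled], group = groups[enrolled],
      period_start_month = starts[w], period_end_month = fus[w],
      treatment_category = category[enrolled],
      cost_sek = round(cost[enrolled], 2),
      utility = round(util[enrolled], 3),
      untreated_nonrecovered_flag = flagged[enrolled]
    )
    truth_chunks[[w]] <- tibble(
      participant_id = ids, group = groups, follow_up = fus[w],
      state = ifelse(enrolled, state, NA_character_),
      flagged = ifelse(enrolled, flagged, NA),
      enrolled = enrolled
    )
  }

  records <- validate_records(bind_rows(rec_chunks), source = "simulate_trial")
  list(records = records,
       truth = list(states = bind_rows(truth_chunks), config = config))
}
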