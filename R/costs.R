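# Cost accrual. Each living state carries an annual cost: the least-severe
# state gets the cost of a child with no behaviour problems; the three more
# severe states get the behaviour-problem base cost plus, for each of PTSD,
# depression, anxiety and ADHD, the condition's annual cost weighted by the
# probability that a child in that state carries the diagnosis. Direct costs
# are health-sector expenditures; the societal perspective adds indirect
# costs (time, caregiver absenteeism, transportation). All costs are annual
# 2018 USD.

PERSPECTIVES <- c("direct", "societal")

#' Annual cost inputs for the severity states
#'
#' @param base_no_problems named vector `c(direct =, indirect =)`: annual
#'   cost of a child with no behaviour problems (state Q1).
#' @param base_behavior_problems same shape: annual base cost of a child
#'   with behaviour problems (states Q2--Q4).
#' @param condition_costs 4x2 matrix (rows `ptsd`, `depression`, `anxiety`,
#'   `adhd`; columns `direct`, `indirect`) of annual per-condition costs.
#' @param prevalence 4x4 matrix of P(condition | state) (conditions x
#'   states), e.g. the `proportion` block of a [tabulate_prevalence()]
#'   result restricted to the state columns.
#' @param include_q1_conditions if `TRUE`, state Q1 also accrues
#'   prevalence-weighted condition costs; the default follows the reference
#'   costing rule (Q1 = base cost only).
#' @param currency_note free-text record of source currency/year and any
#'   conversion factor already applied to the inputs.
#' @return an object of class `cost_inputs`.
#' @export
cost_inputs <- function(base_no_problems, base_behavior_problems,
                        condition_costs, prevalence,
                        include_q1_conditions = FALSE,
                        currency_note = "2018 USD") {
  bn <- unlist(base_no_problems)[c("direct", "indirect")]
  bb <- unlist(base_behavior_problems)[c("direct", "indirect")]
  cc <- as.matrix(condition_costs)
  if (any(is.na(bn)) || any(is.na(bb))) {
    stop_input("base costs need 'direct' and 'indirect' components")
  }
  if (!all(dim(cc) == c(4L, 2L))) {
    stop_input("condition_costs must be 4x2 (", paste(CONDITIONS, collapse = ", "),
               ") x (direct, indirect)")
  }
  cc <- cc[CONDITIONS, c("direct", "indirect")]
  prev <- as.matrix(prevalence)[CONDITIONS, STATE_LEVELS]
  if (any(c(bn, bb, cc) < 0)) stop_input("costs must be >= 0")
  if (any(is.na(prev))) {
    stop_input("prevalence has undefined cells for the costed states")
  }
  if (any(prev < 0 | prev > 1)) {
    stop_input("prevalence entries must be probabilities in [0, 1]")
  }
  structure(list(base_no_problems = bn, base_behavior_problems = bb,
                 condition_costs = cc, prevalence = prev,
                 include_q1_conditions = isTRUE(include_q1_conditions),
                 currency_note = currency_note),
            class = "cost_inputs")
}

#' Apply a currency conversion/inflation factor to cost inputs
#'
#' Multiplies every cost component by `factor` and records the adjustment in
#' the currency note.
#'
#' @param inputs a [cost_inputs()].
#' @param factor positive multiplier.
#' @param note description appended to the currency note.
#' @export
convert_costs <- function(inputs, factor, note = NULL) {
  if (factor <= 0) stop_input("conversion factor must be positive")
  inputs$base_no_problems <- inputs$base_no_problems * factor
  inputs$base_behavior_problems <- inputs$base_behavior_problems * factor
  inputs$condition_costs <- inputs$condition_costs * factor
  inputs$currency_note <- paste0(
    inputs$currency_note, "; x", format(factor),
    if (!is.null(note)) paste0(" (", note, ")")
  )
  inputs
}

# Annual cost of every state (Q1..Q4, Dead) under one perspective.
state_cost_vector <- function(inputs, perspective = PERSPECTIVES) {
  perspective <- match.arg(perspective)
  comp <- if (perspective == "direct") "direct" else c("direct", "indirect")
  base_q1 <- sum(inputs$base_no_problems[comp])
  base_beh <- sum(inputs$base_behavior_problems[comp])
  cond <- rowSums(inputs$condition_costs[, comp, drop = FALSE])
  weighted <- as.numeric(cond %*% inputs$prevalence)  # per state Q1..Q4
  cost <- c(base_q1, rep(base_beh, 3L)) +
    weighted * c(as.numeric(inputs$include_q1_conditions), 1, 1, 1)
  c(stats::setNames(cost, STATE_LEVELS), Dead = 0)
}

#' Annual cost of occupying a severity state
#'
#' @param state state label in `Q1`..`Q4` or `Dead` (vectorised).
#' @param inputs a [cost_inputs()].
#' @param perspective `"direct"` (health sector) or `"societal"`
#'   (direct + indirect).
#' @return annual cost in USD.
#' @export
state_annual_cost <- function(state, inputs, perspective = PERSPECTIVES) {
  cost <- state_cost_vector(inputs, perspective)
  state <- as.character(state)
  if (!all(state %in% names(cost))) {
    stop_input("unknown state: ", paste(setdiff(state, names(cost)), collapse = ", "))
  }
  unname(cost[state])
}

#' Accumulate per-child costs over a Markov trajectory
#'
#' Costs accrue on start-of-cycle occupancy: the total is the sum over
#' cycles t = 0..T-1 of the occupancy-weighted state costs, optionally
#' discounted by `1 / (1 + rate)^t`. No half-cycle correction is applied.
#'
#' @param traj a [run_trajectory()] result.
#' @param inputs a [cost_inputs()].
#' @param perspective `"direct"` or `"societal"`.
#' @param discount_rate annual discount rate (0 = undiscounted, the
#'   default).
#' @return a list with `total` (per-child USD) and `per_cycle` (length-T
#'   vector of discounted cycle costs).
#' @export
accumulate_costs <- function(traj, inputs, perspective = PERSPECTIVES,
                             discount_rate = 0) {
  if (!inherits(traj, "trajectory")) stop_input("traj must be a trajectory")
  if (discount_rate < 0) stop_input("discount_rate must be >= 0")
  cost <- state_cost_vector(inputs, perspective)
  occ <- traj$occupancy[seq_len(traj$horizon), , drop = FALSE]
  per_cycle <- as.numeric(occ %*% cost) /
    (1 + discount_rate)^(0:(traj$horizon - 1L))
  list(total = sum(per_cycle), per_cycle = per_cycle)
}

#' Incremental per-child costs versus a reference scenario
#'
#' @param results named numeric vector (or list) of per-child totals per
#'   scenario.
#' @param reference name of the reference scenario (maps to increment 0).
#' @return named numeric vector of increments, same order as `results`.
#' @export
compare_scenarios <- function(results, reference = "NoDetention") {
  totals <- unlist(results)
  if (!reference %in% names(totals)) {
    stop_input("reference scenario '", reference, "' not present in results")
  }
  totals - totals[[reference]]
}

#' Scale an incremental per-child cost to a hypothetical cohort
#'
#' Exact product of the per-child increment and the cohort size, reported in
#' whole dollars.
#'
#' @param incremental_per_child per-child incremental cost, USD.
#' @param cohort a [cohort_size()] or a plain integer size.
#' @return total USD (whole dollars).
#' @export
scale_to_cohort <- function(incremental_per_child, cohort) {
  size <- if (inherits(cohort, "cohort_size")) cohort$size else cohort
  if (!is_count(size) || size < 1) stop_input("cohort size must be an integer >= 1")
  round(incremental_per_child * size)
}

#' A hypothetical policy-affected cohort
#'
#' Defaults elsewhere in the package use the three reported cohorts: 2,342
#' children (separations reported in June 2018) and 16,790 / 23,725 (annual
#' estimates from 46--65 daily separations).
#'
#' @param label cohort label.
#' @param size number of children (integer >= 1).
#' @export
cohort_size <- function(label, size) {
  if (!is_count(size) || size < 1) stop_input("cohort size must be an integer >= 1")
  structure(list(label = label, size = as.integer(size)),
            class = "cohort_size")
}

default_cohorts <- function() {
  list(cohort_size("Cohort1", 2342L),
       cohort_size("Cohort2", 16790L),
       cohort_size("Cohort3", 23725L))
}
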