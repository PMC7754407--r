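# The assembled cost model: baseline state occupancy -> scenario-shifted
# initial distribution -> Markov trajectory -> per-child cost accrual ->
# incrementals vs No Detention -> budget impact on hypothetical cohorts.
# The per-child confidence interval re-runs the whole pipeline at the lower
# and upper bounds of the per-trauma odds ratio; no other input is varied.

#' Per-child total cost under one scenario
#'
#' Runs baseline -> initial distribution -> Markov trajectory -> cost
#' accrual for a single scenario, horizon and perspective.
#'
#' @param config a validated [load_config()] configuration.
#' @param scenario a [policy_scenario()] (or list with the same fields).
#' @param horizon annual cycles.
#' @param perspective `"direct"` or `"societal"`.
#' @param or_which which bound of the configured odds ratio to use.
#' @return per-child total cost, USD.
#' @export
per_child_total <- function(config, scenario, horizon,
                            perspective = PERSPECTIVES,
                            or_which = c("point", "low", "high")) {
  perspective <- match.arg(perspective)
  or_which <- match.arg(or_which)
  if (!inherits(scenario, "policy_scenario")) {
    scenario <- policy_scenario(scenario$name, scenario$exposed_fraction,
                                scenario$extra_traumas %||% 1L)
  }
  base <- baseline_from_config(config)
  or_value <- switch(or_which,
                     point = config$effect$or,
                     low = config$effect$ci_low %||% config$effect$or,
                     high = config$effect$ci_high %||% config$effect$or)
  init <- initial_distribution(base, scenario, or_value)
  traj <- run_trajectory(init, transition_from_config(config),
                         mortality_from_config(config),
                         config$markov$start_age, horizon)
  accumulate_costs(traj, costs_from_config(config), perspective,
                   config$discount_rate %||% 0)$total
}

#' Base-case per-child totals and incrementals
#'
#' Evaluates every configured scenario at every horizon and perspective,
#' with the per-child interval obtained by re-running the pipeline at the
#' lower and upper bounds of the per-trauma odds ratio.
#'
#' @param config a validated configuration.
#' @param reference reference scenario name for incrementals.
#' @return a data frame with one row per horizon x perspective x scenario:
#'   `per_child_total`, `total_low`, `total_high`, `incremental`,
#'   `incremental_low`, `incremental_high`.
#' @export
run_base_case <- function(config, reference = "NoDetention") {
  scenarios <- scenarios_from_config(config)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  rows <- list()
  for (h in config$markov$horizons) {
    for (p in PERSPECTIVES) {
      tot <- vapply(scenarios, per_child_total, numeric(1),
                    config = config, horizon = h, perspective = p)
      lo <- vapply(scenarios, per_child_total, numeric(1),
                   config = config, horizon = h, perspective = p,
                   or_which = "low")
      hi <- vapply(scenarios, per_child_total, numeric(1),
                   config = config, horizon = h, perspective = p,
                   or_which = "high")
      inc <- compare_scenarios(tot, reference)
      rows[[length(rows) + 1L]] <- data.frame(
        horizon = h, perspective = p, scenario = names(scenarios),
        per_child_total = unname(tot),
        total_low = unname(pmin(lo, hi)), total_high = unname(pmax(lo, hi)),
        incremental = unname(inc),
        incremental_low = unname(pmin(compare_scenarios(lo, reference),
                                      compare_scenarios(hi, reference))),
        incremental_high = unname(pmax(compare_scenarios(lo, reference),
                                       compare_scenarios(hi, reference))),
        row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}

#' Budget-impact table from per-child totals
#'
#' Builds the report-shaped table: per-child totals, per-child incrementals
#' versus the reference scenario, and each incremental scaled to the
#' hypothetical cohorts (whole dollars).
#'
#' @param totals data frame with columns `horizon`, `perspective`,
#'   `scenario`, `per_child_total` (e.g. [run_base_case()] output or a
#'   fixture of reference totals).
#' @param cohorts list of [cohort_size()] (default: the three reported
#'   cohorts of 2,342, 16,790 and 23,725 children).
#' @param reference reference scenario name.
#' @return `totals` with `incremental` and one `<label>_incremental` column
#'   per cohort.
#' @export
budget_impact_table <- function(totals, cohorts = default_cohorts(),
                                reference = "NoDetention") {
  cohorts <- lapply(cohorts, function(x) {
    if (inherits(x, "cohort_size")) x else cohort_size(x$label, x$size)
  })
  out <- list()
  for (h in unique(totals$horizon)) {
    for (p in unique(totals$perspective)) {
      blk <- totals[totals$horizon == h & totals$perspective == p, ,
                    drop = FALSE]
      if (!nrow(blk)) next
      tot <- stats::setNames(blk$per_child_total, blk$scenario)
      blk$incremental <- unname(compare_scenarios(tot, reference))
      for (co in cohorts) {
        blk[[paste0(co$label, "_incremental")]] <-
          vapply(blk$incremental, scale_to_cohort, numeric(1), cohort = co)
      }
      out[[length(out) + 1L]] <- blk
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Fit the policy cost model
#'
#' Top-level entry point: runs the base case for every configured scenario,
#' horizon and perspective, propagates the odds-ratio confidence bounds, and
#' scales incrementals to the hypothetical cohorts.
#'
#' @param config a validated configuration (default: packaged inputs).
#' @param reference reference scenario for incrementals.
#' @return an object of class `policy_cost_model` with components
#'   `base_case`, `budget`, `config`, `reference`.
#' @examples
#' m <- policy_cost_model(load_config())
#' print(m)
#' @export
policy_cost_model <- function(config = load_config(),
                              reference = "NoDetention") {
  if (!inherits(config, "model_config")) config <- validate_config(config)
  base_case <- run_base_case(config, reference)
  budget <- budget_impact_table(
    base_case[, c("horizon", "perspective", "scenario", "per_child_total")],
    lapply(config$cohorts, function(x) cohort_size(x$label, x$size)),
    reference
  )
  structure(list(base_case = base_case, budget = budget, config = config,
                 reference = reference),
            class = "policy_cost_model")
}

#' @export
print.policy_cost_model <- function(x, digits = 0, ...) {
  cat("Policy cost model (reference:", x$reference, ")\n")
  cat("Per-child totals and incrementals (USD):\n")
  df <- x$base_case
  df$per_child_total <- round(df$per_child_total, digits)
  df$incremental <- round(df$incremental, digits)
  print(df[, c("horizon", "perspective", "scenario", "per_child_total",
               "incremental")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.policy_cost_model <- function(object, ...) {
  print(object)
  cat("\nPer-child 95% interval from the odds-ratio bounds:\n")
  df <- object$base_case
  df$per_child_total <- round(df$per_child_total)
  df$ci <- sprintf("[%.0f, %.0f]", df$total_low, df$total_high)
  print(df[, c("horizon", "perspective", "scenario", "per_child_total",
               "ci")], row.names = FALSE)
  cat("\nCohort budget impact (incremental, whole USD):\n")
  bud <- object$budget
  inc_cols <- grep("_incremental$", names(bud), value = TRUE)
  print(bud[, c("horizon", "perspective", "scenario", inc_cols)],
        row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.policy_cost_model <- function(x, ...) x$base_case

#' @export
plot.policy_cost_model <- function(x, horizon = NULL, ...) {
  df <- x$base_case
  horizon <- horizon %||% min(df$horizon)
  df <- df[df$horizon == horizon, ]
  m <- tapply(df$per_child_total, list(df$perspective, df$scenario), mean)
  m <- m[, unique(df$scenario), drop = FALSE]
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "Per-child total cost (USD)",
                    main = paste0("Per-child cost by scenario (", horizon,
                                  "-year horizon)"), ...)
  invisible(x)
}
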