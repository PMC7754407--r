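# Sensitivity analyses: one-way deterministic (tornado), the exposed-
# fraction sweep, and Monte Carlo probabilistic sensitivity analysis. Each
# re-runs the full pipeline with perturbed configuration values addressed by
# dot-paths, so every analysis sees exactly the model the base case uses.

# Evaluate the configured outcome once. outcome "per_child" is the scenario
# per-child total; "incremental" subtracts the reference scenario's total.
pipeline_outcome <- function(config, outcome = c("per_child", "incremental"),
                             scenario_name, perspective, horizon,
                             reference = "NoDetention") {
  outcome <- match.arg(outcome)
  scenarios <- scenarios_from_config(config)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  if (!scenario_name %in% names(scenarios)) {
    stop_input("scenario '", scenario_name, "' not present in configuration")
  }
  tot <- per_child_total(config, scenarios[[scenario_name]], horizon,
                         perspective)
  if (outcome == "per_child") return(tot)
  ref <- per_child_total(config, scenarios[[reference]], horizon, perspective)
  tot - ref
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' For each configured input range, the full pipeline is re-run with only
#' that input set to its low and then its high value; the spread is the
#' absolute difference of the two outcomes. Rows are sorted by spread
#' descending (tornado order).
#'
#' @param config a validated [load_config()] configuration.
#' @param ranges list of ranges, each `list(path =, low =, high =)`;
#'   defaults to `config$dsa$ranges`.
#' @param outcome `"per_child"` total or `"incremental"` versus the
#'   reference scenario; defaults from `config$dsa`.
#' @param scenario,perspective,horizon which pipeline outcome to track;
#'   defaults from `config$dsa`.
#' @return a data frame (parameter, base, low, high, outcome_base,
#'   outcome_low, outcome_high, spread), sorted by spread descending.
#' @export
one_way_dsa <- function(config, ranges = NULL, outcome = NULL,
                        scenario = NULL, perspective = NULL, horizon = NULL) {
  ranges <- ranges %||% config$dsa$ranges
  if (is.null(ranges) || !length(ranges)) {
    stop_input("no DSA ranges supplied or configured")
  }
  outcome <- outcome %||% config$dsa$outcome %||% "per_child"
  scenario <- scenario %||% config$dsa$scenario %||% "ZeroTolerance"
  perspective <- perspective %||% config$dsa$perspective %||% "direct"
  horizon <- horizon %||% config$dsa$horizon %||% config$markov$horizons[1L]
  base_out <- pipeline_outcome(config, outcome, scenario, perspective, horizon)
  rows <- lapply(ranges, function(r) {
    base_val <- config_get(config, r$path)
    if (!(r$low <= base_val && base_val <= r$high)) {
      stop_input("DSA range for '", r$path, "' must satisfy low <= base <= high")
    }
    out_lo <- pipeline_outcome(config_set(config, r$path, r$low),
                               outcome, scenario, perspective, horizon)
    out_hi <- pipeline_outcome(config_set(config, r$path, r$high),
                               outcome, scenario, perspective, horizon)
    data.frame(parameter = r$path, base = base_val, low = r$low,
               high = r$high, outcome_base = base_out,
               outcome_low = out_lo, outcome_high = out_hi,
               spread = abs(out_hi - out_lo))
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$spread), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param dsa a [one_way_dsa()] table.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_tornado <- function(dsa, ...) {
  df <- dsa[order(dsa$spread), , drop = FALSE]
  lo <- df$outcome_low - df$outcome_base
  hi <- df$outcome_high - df$outcome_base
  graphics::barplot(t(cbind(lo, hi)), beside = TRUE, horiz = TRUE,
                    names.arg = df$parameter, las = 1,
                    xlab = "Outcome change from base case (USD)",
                    main = "One-way sensitivity (tornado)", ...)
  invisible(dsa)
}

#' Sweep the exposed-trauma fraction from 0% to 100%
#'
#' Re-runs the pipeline with a single scenario whose exposed fraction takes
#' each value of `fractions` (default 0 to 1 in 10% increments), reporting
#' per-child totals and the incremental versus the 0% run for both
#' perspectives. Because the initial distribution is linear in the mixture
#' weight and cost accrual is linear in the initial distribution, successive
#' increments are exactly equal.
#'
#' @param config a validated configuration.
#' @param fractions exposed fractions in `[0, 1]`.
#' @param horizon annual cycles (defaults from `config$sweep`).
#' @param extra_traumas additional traumas applied to the exposed fraction.
#' @return a data frame (fraction, per_child_direct, per_child_societal,
#'   incremental_direct, incremental_societal).
#' @export
trauma_fraction_sweep <- function(config, fractions = NULL, horizon = NULL,
                                  extra_traumas = 1L) {
  inc <- config$sweep$increment %||% 0.1
  fractions <- fractions %||% seq(0, 1, by = inc)
  if (any(fractions < 0 | fractions > 1)) {
    stop_input("sweep fractions must lie in [0, 1]")
  }
  horizon <- horizon %||% config$sweep$horizon %||% config$markov$horizons[1L]
  totals <- vapply(fractions, function(f) {
    sc <- policy_scenario("sweep", f, extra_traumas)
    c(direct = per_child_total(config, sc, horizon, "direct"),
      societal = per_child_total(config, sc, horizon, "societal"))
  }, numeric(2))
  base <- vapply(c("direct", "societal"), function(p) {
    per_child_total(config, policy_scenario("none", 0, extra_traumas),
                    horizon, p)
  }, numeric(1))
  data.frame(
    fraction = fractions,
    per_child_direct = totals["direct", ],
    per_child_societal = totals["societal", ],
    incremental_direct = totals["direct", ] - base[["direct"]],
    incremental_societal = totals["societal", ] - base[["societal"]]
  )
}

# Draw n values for one PSA parameter specification.
sample_psa_param <- function(param, n) {
  bad <- function(...) stop_input("invalid PSA distribution for '",
                                  param$path, "': ", ...)
  switch(
    param$dist %||% "fixed",
    lognormal = {
      if (is.null(param$meanlog) || is.null(param$sdlog) || param$sdlog < 0) {
        bad("lognormal needs meanlog and sdlog >= 0")
      }
      stats::rlnorm(n, param$meanlog, param$sdlog)
    },
    gamma = {
      if (!is.null(param$mean) && !is.null(param$cv)) {
        if (param$mean <= 0 || param$cv <= 0) bad("gamma needs mean > 0, cv > 0")
        shape <- 1 / param$cv^2
        stats::rgamma(n, shape = shape, rate = shape / param$mean)
      } else if (!is.null(param$shape) && !is.null(param$rate)) {
        if (param$shape <= 0 || param$rate <= 0) bad("gamma needs shape, rate > 0")
        stats::rgamma(n, shape = param$shape, rate = param$rate)
      } else {
        bad("gamma needs (mean, cv) or (shape, rate)")
      }
    },
    beta = {
      if (is.null(param$shape1) || is.null(param$shape2) ||
          param$shape1 <= 0 || param$shape2 <= 0) {
        bad("beta needs shape1 > 0 and shape2 > 0")
      }
      stats::rbeta(n, param$shape1, param$shape2)
    },
    fixed = {
      if (is.null(param$value)) bad("fixed needs a value")
      rep(param$value, n)
    },
    bad("unknown family '", param$dist, "'")
  )
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Samples every configured parameter from its distribution (jointly
#' independent), re-evaluates the full pipeline per iteration, and
#' summarises the per-child and incremental cost distributions. Sampling is
#' seeded and reproducible; all draws are returned.
#'
#' @param config a validated configuration with a `psa` block.
#' @param iterations number of Monte Carlo iterations (default from config).
#' @param seed RNG seed (default from config).
#' @param scenario,perspective,horizon outcome tracked for the incremental
#'   summary; defaults mirror the DSA settings.
#' @return an object of class `psa_result`: `draws` (one row per iteration:
#'   sampled parameters, per-child total, incremental), `summary` (mean, sd,
#'   2.5% and 97.5% quantiles), `iterations`, `seed`.
#' @export
run_psa <- function(config, iterations = NULL, seed = NULL, scenario = NULL,
                    perspective = NULL, horizon = NULL) {
  params <- config$psa$parameters
  if (is.null(params) || !length(params)) {
    stop_input("no PSA parameters configured")
  }
  iterations <- iterations %||% config$psa$iterations %||% 10000L
  if (!is_count(iterations) || iterations < 1) {
    stop_input("iterations must be an integer >= 1")
  }
  seed <- seed %||% config$psa$seed %||% 1L
  scenario <- scenario %||% config$dsa$scenario %||% "ZeroTolerance"
  perspective <- perspective %||% config$dsa$perspective %||% "direct"
  horizon <- horizon %||% config$dsa$horizon %||% config$markov$horizons[1L]
  set.seed(seed)
  draw_mat <- vapply(params, sample_psa_param, numeric(iterations),
                     n = iterations)
  if (iterations == 1L) draw_mat <- matrix(draw_mat, nrow = 1L)
  colnames(draw_mat) <- vapply(params, `[[`, character(1), "path")
  per_child <- numeric(iterations)
  incremental <- numeric(iterations)
  for (i in seq_len(iterations)) {
    cfg_i <- config
    for (j in seq_along(params)) {
      cfg_i <- config_set(cfg_i, params[[j]]$path, unname(draw_mat[i, j]))
    }
    per_child[i] <- pipeline_outcome(cfg_i, "per_child", scenario,
                                     perspective, horizon)
    incremental[i] <- pipeline_outcome(cfg_i, "incremental", scenario,
                                       perspective, horizon)
  }
  draws <- cbind(as.data.frame(draw_mat),
                 per_child_total = per_child, incremental = incremental)
  summarise <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    c(mean = mean(x), sd = stats::sd(x), q2.5 = q[1L], q97.5 = q[2L])
  }
  structure(list(
    draws = draws,
    summary = rbind(per_child_total = summarise(per_child),
                    incremental = summarise(incremental)),
    iterations = iterations, seed = seed,
    scenario = scenario, perspective = perspective, horizon = horizon
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$iterations, "iterations",
      sprintf("(%s, %s perspective, %d-year horizon)\n",
              x$scenario, x$perspective, x$horizon))
  print(round(x$summary, 2))
  invisible(x)
}
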