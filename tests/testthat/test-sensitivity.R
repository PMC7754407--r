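test_that("a degenerate range produces zero spread and base values reproduce the base case", {
  cfg <- load_config()
  base_val <- config_get(cfg, "costs.conditions.ptsd.direct")
  dsa <- one_way_dsa(cfg, ranges = list(
    list(path = "costs.conditions.ptsd.direct",
         low = base_val, high = base_val)
  ))
  expect_equal(dsa$spread, 0)
  expect_equal(dsa$outcome_low, dsa$outcome_base)
  # every parameter at its base value reproduces the base case exactly
  full <- one_way_dsa(cfg, ranges = lapply(cfg$dsa$ranges, function(r) {
    b <- config_get(cfg, r$path)
    list(path = r$path, low = b, high = b)
  }))
  expect_true(all(full$outcome_low == full$outcome_base))
  expect_true(all(full$outcome_high == full$outcome_base))
})

test_that("doubling vs halving one cost matches two direct pipeline evaluations", {
  cfg <- load_config()
  path <- "costs.conditions.depression.direct"
  b <- config_get(cfg, path)
  dsa <- one_way_dsa(cfg, ranges = list(list(path = path, low = b / 2, high = 2 * b)),
                     outcome = "per_child", scenario = "ZeroTolerance",
                     perspective = "direct", horizon = 5)
  # independent oracle: two direct accumulate_costs evaluations
  eval_at <- function(v) {
    c2 <- config_set(cfg, path, v)
    init <- initial_distribution(traumacost:::baseline_from_config(c2),
                                 policy_scenario("ZT", 1),
                                 c2$effect$or)
    traj <- run_trajectory(init,
                           transition_model(do.call(rbind, c2$markov$transition_matrix)),
                           mortality_table(c2$mortality$ages, c2$mortality$rates),
                           c2$markov$start_age, 5)
    accumulate_costs(traj, traumacost:::costs_from_config(c2), "direct")$total
  }
  expect_equal(dsa$spread, abs(eval_at(2 * b) - eval_at(b / 2)),
               tolerance = 1e-10)
})

test_that("the tornado is a non-negative permutation sorted by spread", {
  cfg <- load_config()
  dsa <- one_way_dsa(cfg)
  expect_setequal(dsa$parameter,
                  vapply(cfg$dsa$ranges, `[[`, character(1), "path"))
  expect_true(all(dsa$spread >= 0))
  expect_true(all(diff(dsa$spread) <= 0))
  # under the default cost mix, the depression cost range dominates
  expect_equal(dsa$parameter[1], "costs.conditions.depression.direct")
  expect_error(one_way_dsa(cfg, ranges = list(
    list(path = "costs.not.a.key", low = 0, high = 1))), "not found")
})

test_that("the exposed-fraction sweep is anchored and exactly linear", {
  cfg <- load_config()
  sw <- trauma_fraction_sweep(cfg)
  expect_equal(sw$fraction, seq(0, 1, 0.1))
  expect_equal(sw$incremental_direct[1], 0)
  expect_equal(sw$incremental_societal[1], 0)
  # fraction 1.0 equals the Zero Tolerance incremental of the base pipeline
  bc <- run_base_case(cfg)
  zt5 <- bc[bc$horizon == 5 & bc$scenario == "ZeroTolerance", ]
  expect_equal(sw$incremental_direct[11],
               zt5$incremental[zt5$perspective == "direct"],
               tolerance = 1e-10)
  expect_equal(sw$incremental_societal[11],
               zt5$incremental[zt5$perspective == "societal"],
               tolerance = 1e-10)
  # successive increments are exactly equal (linearity in the mixture weight)
  steps_d <- diff(sw$incremental_direct)
  steps_s <- diff(sw$incremental_societal)
  expect_equal(steps_d, rep(steps_d[1], 10), tolerance = 1e-9)
  expect_equal(steps_s, rep(steps_s[1], 10), tolerance = 1e-9)
  expect_error(trauma_fraction_sweep(cfg, fractions = c(0, 1.2)), "\\[0, 1\\]")
})

test_that("degenerate sampling distributions collapse the PSA to the base case", {
  cfg <- load_config()
  base <- traumacost:::pipeline_outcome(cfg, "per_child", "ZeroTolerance",
                                        "direct", 5)
  cfg$psa$parameters <- list(
    list(path = "effect.or", dist = "fixed", value = cfg$effect$or),
    list(path = "costs.conditions.ptsd.direct", dist = "fixed",
         value = config_get(cfg, "costs.conditions.ptsd.direct"))
  )
  psa <- run_psa(cfg, iterations = 20, seed = 1)
  expect_true(all(psa$draws$per_child_total == psa$draws$per_child_total[1]))
  expect_equal(psa$summary["per_child_total", "mean"], base,
               ignore_attr = TRUE)
  expect_equal(unname(psa$summary["per_child_total", "sd"]), 0)
})

test_that("the fitted lognormal reproduces the odds-ratio interval and seeds reproduce", {
  cfg <- load_config()
  psa <- run_psa(cfg, iterations = 2000, seed = 101)
  or_draws <- psa$draws[["effect.or"]]
  q <- quantile(or_draws, c(0.025, 0.975), names = FALSE)
  # closed-form lognormal quantiles fitted to [1.141, 1.330]
  expect_true(abs(q[1] - 1.141) < 0.01)
  expect_true(abs(q[2] - 1.330) < 0.01)
  psa2 <- run_psa(cfg, iterations = 2000, seed = 101)
  expect_identical(psa$draws, psa2$draws)
  # doubling iterations leaves the mean within Monte Carlo error
  psa4 <- run_psa(cfg, iterations = 4000, seed = 101)
  se <- psa$summary["per_child_total", "sd"] / sqrt(2000)
  expect_true(abs(psa4$summary["per_child_total", "mean"] -
                    psa$summary["per_child_total", "mean"]) < 2 * se)
})

test_that("invalid PSA distribution parameters are rejected", {
  cfg <- load_config()
  cfg$psa$parameters <- list(list(path = "effect.or", dist = "gamma",
                                  mean = -1, cv = 0.2))
  expect_error(run_psa(cfg, iterations = 5), "invalid PSA distribution")
  cfg$psa$parameters <- list(list(path = "effect.or", dist = "cauchy"))
  expect_error(run_psa(cfg, iterations = 5), "unknown family")
})
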