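make_inputs <- function(base_np = c(direct = 1000, indirect = 400),
                        base_bp = c(direct = 2500, indirect = 1300),
                        cond = NULL, prev = NULL, ...) {
  if (is.null(cond)) {
    cond <- matrix(c(2400, 1600, 4800, 2400, 1700, 900, 2100, 1400),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("ptsd", "depression", "anxiety", "adhd"),
                                   c("direct", "indirect")))
  }
  if (is.null(prev)) {
    prev <- traumacost:::default_prevalence_by_state()
  }
  cost_inputs(base_np, base_bp, cond, prev, ...)
}

test_that("state costs follow the base-plus-prevalence-weighted rule", {
  zero_cond <- matrix(0, 4, 2,
                      dimnames = list(c("ptsd", "depression", "anxiety", "adhd"),
                                      c("direct", "indirect")))
  inp <- make_inputs(cond = zero_cond)
  expect_equal(state_annual_cost("Q1", inp, "direct"), 1000)
  expect_equal(state_annual_cost(c("Q2", "Q3", "Q4"), inp, "direct"),
               rep(2500, 3))
  expect_equal(state_annual_cost("Q2", inp, "societal"), 3800)
  expect_equal(state_annual_cost("Dead", inp, "societal"), 0)
})

test_that("a unit-cost state reproduces the hand-computed prevalence dot product", {
  prev <- matrix(0, 4, 4, dimnames = dimnames(traumacost:::default_prevalence_by_state()))
  prev[, "Q3"] <- c(0.5224, 0.2537, 0.1119, 0.0448)
  unit <- matrix(c(100, 0), 4, 2, byrow = TRUE,
                 dimnames = list(rownames(prev), c("direct", "indirect")))
  inp <- make_inputs(base_np = c(direct = 0, indirect = 0),
                     base_bp = c(direct = 0, indirect = 0),
                     cond = unit, prev = prev)
  expect_equal(state_annual_cost("Q3", inp, "direct"), 93.28)
})

test_that("Q1 accrues condition costs only when explicitly enabled", {
  inp <- make_inputs()
  inp_q1 <- make_inputs(include_q1_conditions = TRUE)
  q1_weight <- sum(traumacost:::default_prevalence_by_state()[, "Q1"] *
                     rowSums(inp$condition_costs))
  expect_equal(state_annual_cost("Q1", inp_q1, "societal") -
                 state_annual_cost("Q1", inp, "societal"), q1_weight)
})

test_that("cost accumulation matches closed forms and the cycle-by-cycle oracle", {
  tm <- transition_model(diag(4))
  mort <- mortality_table(13:30, rep(0, 18))
  init <- severity_distribution(c(0.131, 0.382, 0.293, 0.194))
  traj <- run_trajectory(init, tm, mort, 13, 6)
  zero <- make_inputs(base_np = c(direct = 0, indirect = 0),
                      base_bp = c(direct = 0, indirect = 0),
                      cond = matrix(0, 4, 2,
                                    dimnames = list(c("ptsd", "depression",
                                                      "anxiety", "adhd"),
                                                    c("direct", "indirect"))))
  expect_equal(accumulate_costs(traj, zero, "societal")$total, 0)
  # constant distribution, constant costs: total = T x (occupancy . cost)
  inp <- make_inputs()
  acc <- accumulate_costs(traj, inp, "direct")
  expect_equal(acc$total, 6 * acc$per_cycle[1], tolerance = 1e-12)
  # moving trajectory vs independent spreadsheet-style arithmetic
  tm2 <- transition_model(rbind(c(0.9, 0.1, 0, 0), c(0, 0.85, 0.15, 0),
                                c(0, 0, 0.95, 0.05), c(0, 0, 0, 1)))
  mort2 <- mortality_table(13:30, rep(0.002, 18))
  traj2 <- run_trajectory(init, tm2, mort2, 13, 5)
  for (p in c("direct", "societal")) {
    expect_equal(accumulate_costs(traj2, inp, p)$total,
                 oracle_accumulate(traj2, inp, p), tolerance = 1e-12)
  }
  # discounting applies 1/(1+r)^t on cycle costs
  acc_d <- accumulate_costs(traj2, inp, "direct", discount_rate = 0.03)
  expect_equal(acc_d$total, oracle_accumulate(traj2, inp, "direct", 0.03),
               tolerance = 1e-12)
})

test_that("perspectives are additive: societal = direct + indirect-only", {
  inp <- make_inputs()
  indirect_only <- make_inputs(
    base_np = c(direct = unname(inp$base_no_problems["indirect"]), indirect = 0),
    base_bp = c(direct = unname(inp$base_behavior_problems["indirect"]), indirect = 0),
    cond = cbind(direct = inp$condition_costs[, "indirect"], indirect = rep(0, 4))
  )
  tm <- transition_model(rbind(c(0.9, 0.1, 0, 0), c(0, 0.9, 0.1, 0),
                               c(0, 0, 0.9, 0.1), c(0, 0, 0, 1)))
  mort <- mortality_table(13:30, rep(0.001, 18))
  traj <- run_trajectory(severity_distribution(c(0.25, 0.25, 0.25, 0.25)),
                         tm, mort, 13, 8)
  expect_equal(accumulate_costs(traj, inp, "societal")$total,
               accumulate_costs(traj, inp, "direct")$total +
                 accumulate_costs(traj, indirect_only, "direct")$total,
               tolerance = 1e-10)
})

test_that("incremental comparison and cohort scaling are exact arithmetic", {
  inc <- compare_scenarios(c(NoDetention = 23652, FamilyDetention = 24281,
                             ZeroTolerance = 24887))
  expect_equal(unname(inc), c(0, 629, 1235))
  expect_equal(unname(compare_scenarios(c(NoDetention = 33008,
                                          FamilyDetention = 33790,
                                          ZeroTolerance = 34544))),
               c(0, 782, 1536))
  expect_equal(unname(compare_scenarios(c(NoDetention = 5, A = 5, B = 5))),
               c(0, 0, 0))
  expect_error(compare_scenarios(c(A = 1, B = 2)), "reference")
  expect_equal(scale_to_cohort(629, cohort_size("c1", 2342)), 1473118)
  expect_equal(scale_to_cohort(1536, 23725), 36441600)
  expect_equal(scale_to_cohort(0, 99999), 0)
  # linearity of budget scaling
  expect_equal(scale_to_cohort(629, 2342) + scale_to_cohort(1235, 2342),
               scale_to_cohort(629 + 1235, 2342))
})

test_that("currency conversion scales every component and is recorded", {
  inp <- make_inputs()
  conv <- convert_costs(inp, 1.1, note = "inflation to 2018")
  expect_equal(state_annual_cost("Q3", conv, "societal"),
               1.1 * state_annual_cost("Q3", inp, "societal"))
  expect_match(conv$currency_note, "inflation to 2018")
})

test_that("cost-input validation names the failure", {
  expect_error(make_inputs(base_np = c(direct = -1, indirect = 0)), ">= 0")
  prev_na <- traumacost:::default_prevalence_by_state()
  prev_na["ptsd", "Q2"] <- NA
  expect_error(make_inputs(prev = prev_na), "undefined")
})
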