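tm_default <- transition_model(rbind(
  c(0.90, 0.10, 0.00, 0.00),
  c(0.00, 0.90, 0.10, 0.00),
  c(0.00, 0.00, 0.90, 0.10),
  c(0.00, 0.00, 0.00, 1.00)
))
start_dist <- severity_distribution(c(0.131, 0.382, 0.293, 0.194))

test_that("one cycle reduces to its trivial and elementwise-oracle cases", {
  idm <- transition_model(diag(4))
  expect_equal(markov_step(start_dist, idm, 0), start_dist)
  all_dead <- markov_step(start_dist, tm_default, 1)
  expect_equal(all_dead[["Dead"]], 1)
  expect_equal(sum(unclass(all_dead)[1:4]), 0)
  stepped <- markov_step(start_dist, tm_default, 0.001)
  expect_equal(as.numeric(stepped),
               oracle_step(as.numeric(start_dist), tm_default$matrix, 0.001),
               tolerance = 1e-12)
})

test_that("transition-model invariants are enforced", {
  expect_error(transition_model(matrix(0.3, 4, 4)), "sum to 1")
  bad <- rbind(c(1, 0, 0, 0), c(0.1, 0.9, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_error(transition_model(bad, progression_only = TRUE),
               "less severe")
  expect_silent(transition_model(bad, progression_only = FALSE))
  expect_error(mortality_table(1:3, c(0.1, 0.2, 1.5)), "probabilities")
})

test_that("trajectories conserve mass and only accumulate death", {
  mort <- mortality_table(13:30, rep(0.002, 18))
  traj <- run_trajectory(start_dist, tm_default, mort, 13, 10)
  expect_equal(unname(rowSums(traj$occupancy)), rep(1, 11), tolerance = 1e-12)
  expect_true(all(diff(traj$occupancy[, "Dead"]) >= 0))
  # severity ratchet among the living under advancing progression
  living <- traj$occupancy[, 1:4] / (1 - traj$occupancy[, "Dead"])
  for (k in 2:4) {
    expect_true(all(diff(rowSums(living[, k:4, drop = FALSE])) >= -1e-12))
  }
})

test_that("trajectory contracts and degenerate cases hold", {
  mort <- mortality_table(13:30, rep(0, 18))
  expect_error(run_trajectory(start_dist, tm_default, mort, 13, 0),
               "horizon")
  idm <- transition_model(diag(4))
  traj <- run_trajectory(start_dist, idm, mort, 13, 5)
  for (t in 1:6) {
    expect_equal(unname(traj$occupancy[t, ]), as.numeric(start_dist))
  }
  expect_error(run_trajectory(start_dist, tm_default,
                              mortality_table(13:15, rep(0, 3)), 13, 10),
               "does not cover age")
})

test_that("final death mass equals the closed-form survival product", {
  rates <- c(0.001, 0.002, 0.0015, 0.003, 0.0025)
  mort <- mortality_table(13:17, rates)
  traj <- run_trajectory(start_dist, tm_default, mort, 13, 5)
  expect_equal(traj$occupancy[6, "Dead"], 1 - prod(1 - rates),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the cycle operator is linear in the distribution", {
  x <- severity_distribution(c(0.4, 0.3, 0.2, 0.1))
  y <- severity_distribution(c(0.1, 0.2, 0.3, 0.4))
  a <- 0.3
  mix <- severity_distribution(a * as.numeric(x)[1:4] +
                                 (1 - a) * as.numeric(y)[1:4])
  lhs <- markov_step(mix, tm_default, 0.01)
  rhs <- a * as.numeric(markov_step(x, tm_default, 0.01)) +
    (1 - a) * as.numeric(markov_step(y, tm_default, 0.01))
  expect_equal(as.numeric(lhs), rhs, tolerance = 1e-14)
})

test_that("trajectories export as tidy cycle-state-probability CSV", {
  mort <- mortality_table(13:20, rep(0.001, 8))
  traj <- run_trajectory(start_dist, tm_default, mort, 13, 3)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 4 * 5)
  expect_equal(sort(unique(df$state)), sort(c("Q1", "Q2", "Q3", "Q4", "Dead")))
  expect_equal(df$probability[df$cycle == 0 & df$state == "Q1"],
               0.131)
})
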