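# Independent oracles used to cross-check the implementation.

# Direct numerical maximisation of the proportional-odds log-likelihood
# (state ~ trauma_count + age + male), independent of the package's fit.
# Cutpoints are parameterised as (z1, log dz2, log dz3) to keep them ordered.
oracle_polr_fit <- function(cohort) {
  y <- as.integer(traumacost::assign_state(cohort$ios_count))
  X <- cbind(cohort$trauma_count, cohort$age,
             as.integer(cohort$sex == "male"))
  nll <- function(par) {
    beta <- par[1:3]
    z <- cumsum(c(par[4], exp(par[5]), exp(par[6])))
    eta <- drop(X %*% beta)
    p <- stats::plogis(c(z, Inf)[y] - eta) -
      stats::plogis(c(-Inf, z)[y] - eta)
    -sum(log(pmax(p, 1e-300)))
  }
  cum <- cumsum(prop.table(table(factor(y, levels = 1:4))))[1:3]
  start <- c(0, 0, 0, stats::qlogis(cum[1]),
             log(diff(stats::qlogis(cum)))[1:2])
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-16))
  list(beta_trauma = unname(opt$par[1]), or = exp(unname(opt$par[1])),
       value = opt$value)
}

# Direct arithmetic on the three cut-point equations of the cumulative-odds
# shift (living states only).
oracle_shift <- function(p4, or) {
  G <- c(p4[2] + p4[3] + p4[4], p4[3] + p4[4], p4[4])
  Gs <- or * G / (1 - G + or * G)
  c(1 - Gs[1], Gs[1] - Gs[2], Gs[2] - Gs[3], Gs[3])
}

# Explicit elementwise arithmetic for one Markov cycle: transitions among
# living states then proportional mortality.
oracle_step <- function(dist5, P, mort) {
  q <- numeric(4)
  for (j in 1:4) q[j] <- sum(dist5[1:4] * P[, j])
  c(q * (1 - mort), dist5[5] + mort * sum(q))
}

# Spreadsheet-style cycle-by-cycle cost accumulation: state costs computed
# by hand from the inputs, occupancy taken at cycle start.
oracle_accumulate <- function(traj, inputs, perspective, discount = 0) {
  comp <- if (perspective == "direct") "direct" else c("direct", "indirect")
  costs <- numeric(5)
  costs[1] <- sum(inputs$base_no_problems[comp])
  for (s in 2:4) {
    costs[s] <- sum(inputs$base_behavior_problems[comp]) +
      sum(inputs$prevalence[, s] *
            rowSums(inputs$condition_costs[, comp, drop = FALSE]))
  }
  total <- 0
  for (t in seq_len(traj$horizon)) {
    cycle <- sum(traj$occupancy[t, ] * costs) / (1 + discount)^(t - 1)
    total <- total + cycle
  }
  total
}

# A small but fully specified configuration used across tests (placeholder
# magnitudes; structure identical to the packaged default).
test_config <- function(...) {
  cfg <- load_config()
  mods <- list(...)
  for (p in names(mods)) cfg <- config_set(cfg, p, mods[[p]])
  cfg
}
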