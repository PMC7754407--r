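# Progression-only Markov cohort engine. One cycle = one year. Within a
# cycle the living mass first transitions among the four severity states,
# then an age-based fraction of all living mass moves to the absorbing Dead
# state; no extra mortality is attached to more severe states.

#' Annual transition model over the living severity states
#'
#' @param matrix 4x4 row-stochastic matrix of annual transition
#'   probabilities over `Q1`..`Q4` (before mortality).
#' @param progression_only if `TRUE` (advancing progression), entries below
#'   the diagonal must be zero: living mass can only remain or move to a
#'   more severe state.
#' @return an object of class `transition_model`.
#' @export
transition_model <- function(matrix, progression_only = TRUE) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L))) {
    stop_input("transition matrix must be 4x4 over the living states")
  }
  if (any(m < 0)) stop_input("transition probabilities must be >= 0")
  if (any(abs(rowSums(m) - 1) > 1e-12)) {
    stop_input("transition matrix rows must sum to 1 (within 1e-12)")
  }
  if (progression_only && any(m[lower.tri(m)] != 0)) {
    stop_input("progression-only transition matrix cannot move mass to a ",
               "less severe state (below-diagonal entries must be 0)")
  }
  dimnames(m) <- list(STATE_LEVELS, STATE_LEVELS)
  structure(list(matrix = m, progression_only = progression_only),
            class = "transition_model")
}

#' Age-based annual mortality table
#'
#' @param ages integer vector of ages in years.
#' @param rates annual probability of death at each age, in `[0, 1]`.
#' @return an object of class `mortality_table`.
#' @export
mortality_table <- function(ages, rates) {
  if (length(ages) != length(rates)) stop_input("ages and rates must align")
  if (any(rates < 0 | rates > 1)) {
    stop_input("mortality rates must be probabilities in [0, 1]")
  }
  structure(list(ages = as.integer(ages), rates = as.numeric(rates)),
            class = "mortality_table")
}

mortality_rate <- function(mort, age) {
  i <- match(age, mort$ages)
  if (any(is.na(i))) {
    stop_input("mortality table does not cover age ",
               paste(age[is.na(i)], collapse = ", "),
               "; extend the table to the ages reachable within the horizon")
  }
  mort$rates[i]
}

#' Advance a severity distribution by one annual cycle
#'
#' Living mass transitions among `Q1`..`Q4` by the transition matrix, then a
#' fraction `mort` of all living mass moves to the absorbing Dead state.
#'
#' @param dist a [severity_distribution()].
#' @param tm a [transition_model()].
#' @param mort annual death probability for this cycle.
#' @return the next-cycle `severity_distribution`.
#' @export
markov_step <- function(dist, tm, mort) {
  dist <- as_distribution(dist)
  if (!inherits(tm, "transition_model")) tm <- transition_model(tm)
  if (mort < 0 || mort > 1) stop_input("mort must be a probability")
  q <- as.numeric(unclass(dist)[1:4] %*% tm$matrix)
  dead <- dist[["Dead"]] + mort * sum(q)
  severity_distribution(q * (1 - mort), dead)
}

#' Run the Markov cohort model over an annual horizon
#'
#' Applies [markov_step()] once per year, advancing the representative
#' cohort age by one year per cycle; mortality for cycle t uses the age at
#' the start of that cycle.
#'
#' @param init initial [severity_distribution()].
#' @param tm a [transition_model()].
#' @param mort a [mortality_table()].
#' @param start_age representative cohort age at model start, years.
#' @param horizon number of annual cycles (>= 1).
#' @return an object of class `trajectory`: `occupancy` is a
#'   `(horizon + 1) x 5` matrix of distributions at cycle boundaries
#'   t = 0..horizon, `ages` the cohort age at each boundary.
#' @export
run_trajectory <- function(init, tm, mort, start_age, horizon) {
  init <- as_distribution(init)
  if (!is_count(horizon) || horizon < 1) {
    stop_input("horizon must be an integer >= 1")
  }
  rates <- mortality_rate(mort, start_age + 0:(horizon - 1L))
  occ <- matrix(NA_real_, nrow = horizon + 1L, ncol = 5L,
                dimnames = list(NULL, DIST_STATES))
  occ[1L, ] <- unclass(init)
  d <- init
  for (t in seq_len(horizon)) {
    d <- markov_step(d, tm, rates[t])
    occ[t + 1L, ] <- unclass(d)
  }
  structure(list(occupancy = occ, ages = start_age + 0:horizon,
                 horizon = as.integer(horizon)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Markov trajectory over", x$horizon, "annual cycles (ages",
      x$ages[1L], "to", x$ages[length(x$ages)], ")\n")
  print(round(x$occupancy, 4))
  invisible(x)
}

#' Export a trajectory as tidy CSV (cycle, state, probability)
#'
#' @param x a `trajectory`.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(x, path) {
  df <- data.frame(
    cycle = rep(0:x$horizon, times = 5L),
    state = rep(DIST_STATES, each = x$horizon + 1L),
    probability = as.vector(x$occupancy)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
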