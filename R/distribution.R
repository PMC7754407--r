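# Severity-state distributions and the policy-scenario shift.
#
# A policy that exposes a fraction of children to one additional trauma is
# modelled by multiplying, at every quartile cut k, the cumulative odds of
# being ABOVE state k by OR^k_traumas, then mixing the shifted distribution
# with the baseline in proportion to the exposed fraction. This is the
# proportional-odds reading of "higher odds of starting in a more severe
# state"; the absorbing Dead state is untouched.

DIST_STATES <- c(STATE_LEVELS, "Dead")

#' Construct a severity-state distribution
#'
#' @param q probabilities over the four living states `Q1`..`Q4`.
#' @param dead probability mass in the absorbing Dead state (0 at model
#'   start).
#' @return a named numeric vector of class `severity_distribution` over
#'   `Q1`, `Q2`, `Q3`, `Q4`, `Dead`, summing to 1 within `1e-12`.
#' @examples
#' severity_distribution(c(60, 175, 134, 89) / 458)
#' @export
severity_distribution <- function(q, dead = 0) {
  if (length(q) == 5L && is.null(names(q))) {
    dead <- q[5L]
    q <- q[1:4]
  }
  x <- c(as.numeric(q), as.numeric(dead))
  if (length(x) != 5L) stop_input("need four living-state probabilities plus Dead")
  if (any(x < 0)) stop_input("severity distribution entries must be >= 0")
  if (abs(sum(x) - 1) > 1e-12) {
    stop_input("severity distribution must sum to 1 (got ",
               format(sum(x), digits = 15), ")")
  }
  names(x) <- DIST_STATES
  class(x) <- "severity_distribution"
  x
}

as_distribution <- function(x) {
  if (inherits(x, "severity_distribution")) x else severity_distribution(x)
}

#' @export
print.severity_distribution <- function(x, ...) {
  print(round(unclass(x), 6))
  invisible(x)
}

#' Shift a severity distribution by a per-trauma odds ratio
#'
#' For each quartile cut k, the cumulative odds of being above state k among
#' the living, `G_k / (1 - G_k)` with `G_k = P(state > k | alive)`, are
#' multiplied by `or_value^k_traumas`; the shifted distribution is recovered
#' from the transformed cumulative probabilities. Dead mass is unchanged.
#' Multiple extra traumas compose multiplicatively on the odds scale.
#'
#' @param base a [severity_distribution()].
#' @param or_value odds ratio per additional trauma (> 0).
#' @param k_traumas number of additional traumas applied (>= 0).
#' @return the shifted `severity_distribution`.
#' @export
shift_distribution <- function(base, or_value, k_traumas = 1L) {
  base <- as_distribution(base)
  if (!is.numeric(or_value) || length(or_value) != 1L || or_value <= 0) {
    stop_input("or_value must be a single positive number")
  }
  if (!is_count(k_traumas)) stop_input("k_traumas must be a non-negative integer")
  if (k_traumas == 0L || or_value == 1) return(base)
  dead <- base[["Dead"]]
  living <- 1 - dead
  if (living <= 0) return(base)
  cond <- unclass(base)[1:4] / living
  # survival above each cut: G_k = P(state > k | alive), k = 1..3
  G <- rev(cumsum(rev(cond)))[2:4]
  r <- or_value^k_traumas
  Gs <- r * G / (1 - G + r * G)
  shifted <- c(1 - Gs[1L], Gs[1L] - Gs[2L], Gs[2L] - Gs[3L], Gs[3L])
  severity_distribution(shifted * living, dead)
}

#' Define a policy scenario
#'
#' A scenario is named by the border-control policy it represents and states
#' what fraction of children are assumed to experience `extra_traumas`
#' additional policy-related traumas: 0% under No Detention, 50% under
#' Family Detention, 100% under Zero Tolerance.
#'
#' @param name scenario label.
#' @param exposed_fraction proportion exposed to the additional trauma(s).
#' @param extra_traumas number of additional traumas for the exposed (>= 0).
#' @export
policy_scenario <- function(name, exposed_fraction, extra_traumas = 1L) {
  if (!is.numeric(exposed_fraction) || exposed_fraction < 0 ||
      exposed_fraction > 1) {
    stop_input("exposed_fraction must lie in [0, 1]")
  }
  if (!is_count(extra_traumas)) {
    stop_input("extra_traumas must be a non-negative integer")
  }
  structure(list(name = name, exposed_fraction = exposed_fraction,
                 extra_traumas = as.integer(extra_traumas)),
            class = "policy_scenario")
}

default_scenarios <- function() {
  list(policy_scenario("NoDetention", 0),
       policy_scenario("FamilyDetention", 0.5),
       policy_scenario("ZeroTolerance", 1))
}

#' Initial state distribution under a policy scenario
#'
#' Mixture `(1 - f) * base + f * shift_distribution(base, OR, extra)` where
#' `f` is the scenario's exposed fraction. With `f = 0` (No Detention) the
#' baseline distribution is returned unchanged.
#'
#' @param base baseline [severity_distribution()] (the unexposed cohort).
#' @param scenario a [policy_scenario()].
#' @param effect a [trauma_effect()] or a single odds ratio.
#' @param which for a `trauma_effect`, which bound to use: the point estimate
#'   or a confidence bound (used to propagate the OR interval through the
#'   cost model).
#' @return the scenario's initial `severity_distribution`.
#' @export
initial_distribution <- function(base, scenario, effect,
                                 which = c("point", "low", "high")) {
  base <- as_distribution(base)
  which <- match.arg(which)
  or_value <- if (inherits(effect, "trauma_effect")) {
    switch(which, point = effect$or_point, low = effect$or_low,
           high = effect$or_high)
  } else {
    as.numeric(effect)
  }
  f <- scenario$exposed_fraction
  if (f == 0) return(base)
  shifted <- shift_distribution(base, or_value, scenario$extra_traumas)
  severity_distribution((1 - f) * unclass(base)[1:4] +
                          f * unclass(shifted)[1:4],
                        base[["Dead"]])
}
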