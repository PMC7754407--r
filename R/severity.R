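# Severity stratification and the trauma dose-response fit.
#
# The severity states are quartiles of the count of endorsed functional-
# impairment (IOS) items: Q1 = 0 items, Q2 = 1-2, Q3 = 3-4, Q4 = 5 or more.
# The dose-response is a proportional-odds (cumulative logit) regression of
# state on the number of confirmed trauma types, adjusted for age and sex;
# its exponentiated trauma coefficient is the per-trauma odds ratio of
# occupying a more severe state.

#' Assign the ordinal severity state from an endorsed-item count
#'
#' @param ios_count non-negative integer vector of endorsed item counts.
#' @return an ordered factor with levels `Q1 < Q2 < Q3 < Q4`.
#' @examples
#' assign_state(c(0, 2, 4, 5))
#' @export
assign_state <- function(ios_count) {
  if (any(is.na(ios_count)) || any(ios_count < 0)) {
    stop_input("ios_count must be non-negative")
  }
  idx <- 1L + findInterval(ios_count, c(1, 3, 5))
  factor(STATE_LEVELS[idx], levels = STATE_LEVELS, ordered = TRUE)
}

#' Tabulate state-conditional prevalence of the four modelled conditions
#'
#' Counts and proportions of PTSD, depression, anxiety and ADHD within each
#' severity state and in the full sample. Proportions are kept at full
#' precision; the print method rounds to two decimals in percent.
#'
#' @param cohort a `trauma_cohort` or data frame with `ios_count` and logical
#'   condition columns `ptsd`, `depression`, `anxiety`, `adhd`.
#' @return an object of class `prevalence_table` with components `counts`
#'   (conditions x states + `full` column), `state_n`, `n`, `proportion`
#'   (same shape as `counts`; `NA` for empty strata, which are listed in
#'   `empty_states`).
#' @export
tabulate_prevalence <- function(cohort) {
  if (nrow(cohort) == 0L) stop_input("cohort must be non-empty")
  state <- assign_state(cohort$ios_count)
  state_n <- as.integer(table(state))
  names(state_n) <- STATE_LEVELS
  counts <- vapply(STATE_LEVELS, function(s) {
    vapply(CONDITIONS, function(cond) sum(cohort[[cond]][state == s]),
           integer(1))
  }, integer(4))
  counts <- cbind(counts, full = rowSums(counts))
  denom <- c(state_n, full = nrow(cohort))
  proportion <- sweep(counts, 2L, denom, "/")
  proportion[, denom == 0L] <- NA_real_
  structure(list(
    counts = counts, state_n = state_n, n = nrow(cohort),
    proportion = proportion,
    empty_states = STATE_LEVELS[state_n == 0L]
  ), class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("Prevalence by severity state (n =", x$n, ")\n")
  cat("  state n:", paste(names(x$state_n), x$state_n, collapse = ", "), "\n")
  pct <- round(100 * x$proportion, 2)
  out <- matrix(paste0(x$counts, " (", pct, "%)"),
                nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(out, quote = FALSE)
  if (length(x$empty_states)) {
    cat("  empty strata (prevalence undefined):",
        paste(x$empty_states, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a prevalence table as CSV
#'
#' Mirrors the reference report layout: one row per condition, with count and
#' percentage columns for the full sample and each state.
#'
#' @param x a `prevalence_table`.
#' @param path output file path.
#' @export
write_prevalence_csv <- function(x, path) {
  cols <- c("full", STATE_LEVELS)
  df <- data.frame(condition = rownames(x$counts))
  for (s in cols) {
    df[[paste0(s, "_n")]] <- x$counts[, s]
    df[[paste0(s, "_pct")]] <- round(100 * x$proportion[, s], 2)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-trauma odds ratio with confidence bounds
#'
#' Container for the multiplicative effect of one additional confirmed
#' trauma type on the cumulative odds of occupying a more severe state.
#'
#' @param or_point point estimate (odds ratio per additional trauma type).
#' @param or_low,or_high 95% confidence bounds.
#' @param covariates character vector naming the adjustment set.
#' @export
trauma_effect <- function(or_point, or_low = or_point, or_high = or_point,
                          covariates = c("age", "sex")) {
  if (!(or_low > 0 && or_low <= or_point && or_point <= or_high)) {
    stop_input("trauma effect requires 0 < or_low <= or_point <= or_high")
  }
  structure(list(or_point = or_point, or_low = or_low, or_high = or_high,
                 covariates = covariates),
            class = "trauma_effect")
}

#' @export
print.trauma_effect <- function(x, ...) {
  cat(sprintf("Per-trauma odds ratio %.3f, 95%% CI [%.3f, %.3f]",
              x$or_point, x$or_low, x$or_high))
  if (length(x$covariates)) {
    cat(", adjusted for", paste(x$covariates, collapse = " and "))
  }
  cat("\n")
  invisible(x)
}

#' Export a trauma effect as JSON
#'
#' @param x a `trauma_effect` or `severity_fit`.
#' @param path output file path.
#' @param n sample size to record (taken from a fit automatically).
#' @export
write_effect_json <- function(x, path, n = NA_integer_) {
  if (inherits(x, "severity_fit")) {
    n <- x$n
    x <- x$effect
  }
  jsonlite::write_json(
    list(or = x$or_point, ci_low = x$or_low, ci_high = x$or_high, n = n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Fit the proportional-odds trauma dose-response model
#'
#' Maximum-likelihood cumulative-logit (proportional-odds) regression of the
#' severity state on the trauma-type count, adjusted for age and sex. The
#' model is parameterised so that an odds ratio above 1 means higher odds of
#' a MORE severe state per additional trauma type; internally the cumulative
#' probabilities are `P(state <= k)` and the linear predictor enters with a
#' negative sign, which is the usual sign flip of this parameterisation.
#' The 95% interval is a Wald interval on the log-odds scale, exponentiated.
#'
#' Records with a missing model variable are excluded listwise.
#'
#' @param cohort a `trauma_cohort` or compatible data frame.
#' @param adjust covariates to adjust for (subset of `c("age", "sex")`).
#' @return an object of class `severity_fit` with components `effect` (a
#'   [trauma_effect()]), `coefficients`, `cutpoints`, `vcov`, `n`, `logLik`
#'   and the underlying `polr` fit.
#' @export
fit_severity_model <- function(cohort, adjust = c("age", "sex")) {
  vars <- c("ios_count", "trauma_count", adjust)
  df <- as.data.frame(cohort)[, vars, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$state <- assign_state(df$ios_count)
  if (length(unique(df$state)) < 2L) {
    stop_input("severity fit requires at least 2 occupied states")
  }
  if (length(unique(df$trauma_count)) < 2L) {
    stop_input("severity fit requires non-constant trauma_count")
  }
  rhs <- paste(c("trauma_count", adjust), collapse = " + ")
  fml <- stats::as.formula(paste("state ~", rhs))
  fit <- tryCatch(
    MASS::polr(fml, data = df, Hess = TRUE,
               control = list(reltol = 1e-14, maxit = 1000)),
    error = function(e) {
      stop_input("proportional-odds estimation failed (possible separation ",
                 "or degenerate data): ", conditionMessage(e))
    }
  )
  beta <- stats::coef(fit)[["trauma_count"]]
  se <- sqrt(stats::vcov(fit)["trauma_count", "trauma_count"])
  z <- stats::qnorm(0.975)
  effect <- trauma_effect(exp(beta), exp(beta - z * se), exp(beta + z * se),
                          covariates = adjust)
  structure(list(
    effect = effect,
    coefficients = stats::coef(fit),
    cutpoints = fit$zeta,
    vcov = stats::vcov(fit),
    n = nrow(df),
    logLik = as.numeric(stats::logLik(fit)),
    polr = fit
  ), class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat("Proportional-odds severity model (n =", x$n, ")\n")
  print(x$effect)
  invisible(x)
}

#' @export
summary.severity_fit <- function(object, ...) {
  s <- summary(object$polr)
  cat("Proportional-odds severity model (n =", object$n, ")\n")
  print(object$effect)
  cat("\nCoefficients (log cumulative odds of a more severe state):\n")
  print(s$coefficients)
  invisible(s)
}

#' @export
coef.severity_fit <- function(object, ...) object$coefficients

#' @export
vcov.severity_fit <- function(object, ...) object$vcov

#' @export
confint.severity_fit <- function(object, parm = "trauma_count",
                                 level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients[parm]
  se <- sqrt(diag(object$vcov)[parm])
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- paste(100 * c((1 - level) / 2, 1 - (1 - level) / 2), "%")
  out
}

#' @export
predict.severity_fit <- function(object, newdata, ...) {
  stats::predict(object$polr, newdata = newdata, ...)
}

#' @export
logLik.severity_fit <- function(object, ...) stats::logLik(object$polr)
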