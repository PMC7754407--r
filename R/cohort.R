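# Synthetic cohort generation calibrated to a clinically referred,
# trauma-exposed migrant youth sample. Each child carries age, sex, a count
# of confirmed trauma types, a count of endorsed functional-impairment (IOS)
# items, and four clinician-diagnosis flags. Severity is induced through a
# proportional-odds model on the latent quartile state, so the generator and
# the downstream cumulative-logit fit share one data-generating mechanism.

STATE_LEVELS <- c("Q1", "Q2", "Q3", "Q4")
CONDITIONS <- c("ptsd", "depression", "anxiety", "adhd")

# Item-count bins defining the four severity states: 0, 1-2, 3-4, >= 5 items.
IOS_BIN_LOW <- c(Q1 = 0L, Q2 = 1L, Q3 = 3L, Q4 = 5L)
IOS_BIN_HIGH <- c(Q1 = 0L, Q2 = 2L, Q3 = 4L, Q4 = 14L)

# Reference per-state sample sizes and per-state diagnosis counts of the
# source sample (n = 458): states 60/175/134/89; rows ptsd/depression/
# anxiety/adhd.
REFERENCE_STATE_N <- c(Q1 = 60L, Q2 = 175L, Q3 = 134L, Q4 = 89L)
REFERENCE_CONDITION_COUNTS <- matrix(
  c(21L, 60L, 70L, 44L,
    7L, 32L, 34L, 36L,
    4L, 12L, 15L, 8L,
    1L, 2L, 6L, 1L),
  nrow = 4L, byrow = TRUE,
  dimnames = list(CONDITIONS, STATE_LEVELS)
)

default_prevalence_by_state <- function() {
  sweep(REFERENCE_CONDITION_COUNTS, 2L, REFERENCE_STATE_N, "/")
}

#' Specification of the synthetic-cohort data-generating process
#'
#' Defaults reproduce the marginal statistics of the reference sample of 458
#' trauma-exposed migrant children: age normal(13, 4) rounded and clamped to
#' 3--20 years, 43.0% male, trauma-type count from a moment-matched negative
#' binomial (mean 3.6, SD 2.3) truncated to 0--20, severity quartile from a
#' proportional-odds model with per-trauma log odds `log(1.232)`, and
#' state-conditional diagnosis prevalence from the reference sample.
#'
#' With `cutpoints = "auto"` the three cumulative-logit intercepts are solved
#' numerically so that the marginal state shares implied by the covariate
#' distribution equal `target_shares` (default 60/175/134/89 out of 458).
#'
#' @param n cohort size (>= 1).
#' @param age_mean,age_sd age distribution in years before rounding/clamping.
#' @param prop_male proportion male; sex is coded male = 1 in the linear
#'   predictor.
#' @param trauma_mean,trauma_sd moments of the untruncated trauma-type count.
#' @param trauma_max upper truncation bound for the trauma-type count.
#' @param beta_trauma,beta_age,beta_sex coefficients of the proportional-odds
#'   linear predictor (log cumulative odds of a more severe state).
#' @param cutpoints `"auto"` or three strictly increasing numbers, the logits
#'   of P(state <= k) at zero linear predictor.
#' @param target_shares four probabilities summing to 1; only used when
#'   `cutpoints = "auto"`.
#' @param prevalence_by_state 4x4 matrix of P(condition | state), rows
#'   `ptsd`, `depression`, `anxiety`, `adhd`, columns `Q1`..`Q4`.
#' @param seed integer RNG seed; identical spec and seed give identical
#'   cohorts.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [summarize_cohort()]
#' @export
cohort_spec <- function(n = 458L,
                        age_mean = 13, age_sd = 4,
                        prop_male = 0.430,
                        trauma_mean = 3.6, trauma_sd = 2.3,
                        trauma_max = 20L,
                        beta_trauma = log(1.232),
                        beta_age = 0, beta_sex = 0,
                        cutpoints = "auto",
                        target_shares = as.numeric(REFERENCE_STATE_N) / sum(REFERENCE_STATE_N),
                        prevalence_by_state = default_prevalence_by_state(),
                        seed = 20180401L) {
  if (!is_count(n) || n < 1) stop_input("cohort size n must be an integer >= 1")
  if (!is.numeric(prop_male) || prop_male < 0 || prop_male > 1) {
    stop_input("prop_male must be a probability in [0, 1]")
  }
  if (trauma_sd <= 0 || age_sd <= 0) stop_input("age_sd and trauma_sd must be positive")
  prevalence_by_state <- as.matrix(prevalence_by_state)
  if (!all(dim(prevalence_by_state) == c(4L, 4L))) {
    stop_input("prevalence_by_state must be a 4x4 matrix (conditions x states)")
  }
  if (any(prevalence_by_state < 0 | prevalence_by_state > 1)) {
    stop_input("prevalence_by_state entries must be probabilities in [0, 1]")
  }
  dimnames(prevalence_by_state) <- list(CONDITIONS, STATE_LEVELS)
  if (is.numeric(cutpoints)) {
    if (length(cutpoints) != 3L || any(diff(cutpoints) <= 0)) {
      stop_input("cutpoints must be three strictly increasing numbers")
    }
  } else if (!identical(cutpoints, "auto")) {
    stop_input("cutpoints must be \"auto\" or three increasing numbers")
  }
  if (abs(sum(target_shares) - 1) > 1e-8 || any(target_shares <= 0)) {
    stop_input("target_shares must be positive and sum to 1")
  }
  spec <- structure(
    list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
         prop_male = prop_male, trauma_mean = trauma_mean,
         trauma_sd = trauma_sd, trauma_max = as.integer(trauma_max),
         beta_trauma = beta_trauma, beta_age = beta_age, beta_sex = beta_sex,
         cutpoints = cutpoints, target_shares = target_shares,
         prevalence_by_state = prevalence_by_state,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "cohort_spec"
  )
  if (identical(cutpoints, "auto")) {
    spec$cutpoints <- calibrate_cutpoints(spec)
  }
  spec
}

# pmf of the rounded, clamped age distribution on 3..20 years
age_pmf <- function(spec) {
  ages <- 3:20
  p <- stats::pnorm(ages + 0.5, spec$age_mean, spec$age_sd) -
    stats::pnorm(ages - 0.5, spec$age_mean, spec$age_sd)
  p[1L] <- stats::pnorm(3.5, spec$age_mean, spec$age_sd)
  p[length(p)] <- 1 - stats::pnorm(19.5, spec$age_mean, spec$age_sd)
  names(p) <- ages
  p
}

# pmf of the trauma-type count: negative binomial matched by moments to
# (mean, sd), truncated to 0..trauma_max; degrades to Poisson when the
# requested variance does not exceed the mean.
trauma_pmf <- function(spec) {
  k <- 0:spec$trauma_max
  v <- spec$trauma_sd^2
  if (v > spec$trauma_mean) {
    size <- spec$trauma_mean^2 / (v - spec$trauma_mean)
    p <- stats::dnbinom(k, size = size, mu = spec$trauma_mean)
  } else {
    p <- stats::dpois(k, spec$trauma_mean)
  }
  p <- p / sum(p)
  names(p) <- k
  p
}

# Solve the three cumulative-logit intercepts so the marginal state shares,
# averaged over the (independent) age, sex and trauma-count distributions,
# hit the target cumulative shares exactly.
calibrate_cutpoints <- function(spec) {
  ta <- trauma_pmf(spec)
  aa <- age_pmf(spec)
  grid <- expand.grid(trauma = as.integer(names(ta)),
                      age = as.integer(names(aa)),
                      male = c(0, 1))
  w <- ta[as.character(grid$trauma)] * aa[as.character(grid$age)] *
    ifelse(grid$male == 1, spec$prop_male, 1 - spec$prop_male)
  eta <- spec$beta_trauma * grid$trauma + spec$beta_age * grid$age +
    spec$beta_sex * grid$male
  cum_target <- cumsum(spec$target_shares)[1:3]
  vapply(cum_target, function(tk) {
    stats::uniroot(function(c) sum(w * stats::plogis(c - eta)) - tk,
                   interval = c(-60, 60), tol = 1e-12)$root
  }, numeric(1))
}

#' Generate a synthetic cohort of trauma-exposed children
#'
#' Draws `spec$n` child records. The severity quartile of each child is drawn
#' from the proportional-odds model
#' `logit P(state <= k) = cutpoint_k - (beta_trauma * trauma + beta_age * age
#' + beta_sex * male)`; the endorsed item count is then drawn uniformly within
#' the quartile's bin (Q1: 0; Q2: 1--2; Q3: 3--4; Q4: 5--14), and the four
#' diagnosis flags are drawn independently with the state-conditional
#' prevalences.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `trauma_cohort` with columns `age`, `sex`
#'   (factor, levels `female`/`male`), `trauma_count`, `ios_count`, and
#'   logical columns `ptsd`, `depression`, `anxiety`, `adhd`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200, seed = 1))
#' summarize_cohort(cohort)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n
  if (!is.null(spec$seed)) set.seed(spec$seed)
  aa <- age_pmf(spec)
  ta <- trauma_pmf(spec)
  age <- sample(as.integer(names(aa)), n, replace = TRUE, prob = aa)
  male <- stats::rbinom(n, 1L, spec$prop_male)
  trauma <- sample(as.integer(names(ta)), n, replace = TRUE, prob = ta)
  eta <- spec$beta_trauma * trauma + spec$beta_age * age + spec$beta_sex * male
  u <- stats::runif(n)
  cum1 <- stats::plogis(spec$cutpoints[1L] - eta)
  cum2 <- stats::plogis(spec$cutpoints[2L] - eta)
  cum3 <- stats::plogis(spec$cutpoints[3L] - eta)
  state <- 1L + (u > cum1) + (u > cum2) + (u > cum3)
  lo <- IOS_BIN_LOW[state]
  hi <- IOS_BIN_HIGH[state]
  ios <- pmin(lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L))), hi)
  flags <- vapply(CONDITIONS, function(cond) {
    stats::rbinom(n, 1L, spec$prevalence_by_state[cond, state]) == 1L
  }, logical(n))
  if (n == 1L) flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, CONDITIONS))
  cohort <- data.frame(
    age = age,
    sex = factor(ifelse(male == 1L, "male", "female"),
                 levels = c("female", "male")),
    trauma_count = trauma,
    ios_count = ios
  )
  cohort <- cbind(cohort, as.data.frame(flags))
  class(cohort) <- c("trauma_cohort", "data.frame")
  attr(cohort, "spec") <- spec
  cohort
}

#' Summarise a cohort against the reference demographic table
#'
#' @param cohort a `trauma_cohort` (or any data frame with the same columns).
#' @return a list of class `cohort_summary`: `n`, `age_mean`, `age_sd`,
#'   `prop_male`, `prop_female`, `trauma_mean`, `trauma_sd`, and `state_share`
#'   (named vector over `Q1`..`Q4`).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop_input("cohort must be non-empty")
  state <- assign_state(cohort$ios_count)
  share <- as.numeric(table(state)) / nrow(cohort)
  names(share) <- STATE_LEVELS
  structure(list(
    n = nrow(cohort),
    age_mean = mean(cohort$age),
    age_sd = stats::sd(cohort$age),
    prop_male = mean(cohort$sex == "male"),
    prop_female = mean(cohort$sex == "female"),
    trauma_mean = mean(cohort$trauma_count),
    trauma_sd = stats::sd(cohort$trauma_count),
    state_share = share
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n =", x$n, ")\n")
  cat(sprintf("  age: mean %.2f (SD %.2f) years\n", x$age_mean, x$age_sd))
  cat(sprintf("  sex: %.1f%% male / %.1f%% female\n",
              100 * x$prop_male, 100 * x$prop_female))
  cat(sprintf("  trauma types: mean %.2f (SD %.2f)\n",
              x$trauma_mean, x$trauma_sd))
  cat("  severity state shares:\n")
  print(round(100 * x$state_share, 1))
  invisible(x)
}

#' Write a cohort to disk
#'
#' `write_cohort_csv` writes one row per child with a header;
#' `write_cohort_jsonl` writes one JSON object per line.
#'
#' @param cohort a `trauma_cohort`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  df <- as.data.frame(cohort)
  df$sex <- as.character(df$sex)
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
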