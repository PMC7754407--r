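# Configuration loading and validation. The whole pipeline is driven by one
# nested configuration (YAML primary, JSON accepted) whose blocks mirror the
# role of the reference model-inputs table: generator marginals, the
# per-trauma odds ratio, baseline state occupancy, scenarios, transition and
# mortality inputs, annual costs, budget cohorts, and sensitivity settings.

KNOWN_CONFIG_KEYS <- c(
  "meta", "cohort", "effect", "baseline_states", "prevalence_counts",
  "scenarios", "markov", "mortality", "costs", "discount_rate", "cohorts",
  "dsa", "sweep", "psa", "provenance"
)

#' Path of the packaged default configuration
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "traumacost",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads YAML (or JSON, by file extension), applies defaults, and validates
#' the schema: unknown top-level keys raise a warning naming them; schema
#' violations (negative costs, non-stochastic transition rows, fractions
#' outside `[0, 1]`, ...) raise an error naming the offending key. The
#' returned list carries a `metadata` attribute recording the source path
#' and the provenance (reference-derived vs placeholder) of input blocks.
#'
#' @param path configuration file; defaults to the packaged configuration.
#' @return a validated configuration list of class `model_config`.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(config, source = path)
}

#' @rdname load_config
#' @param config a configuration list to validate in place.
#' @param source optional source label recorded in metadata.
#' @export
validate_config <- function(config, source = "<in-memory>") {
  if (!is.list(config)) stop_input("configuration must be a list")
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown)) {
    warning("ignoring unknown configuration keys: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  required <- c("effect", "baseline_states", "scenarios", "markov",
                "mortality", "costs")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop_input("configuration is missing required keys: ",
               paste(missing, collapse = ", "))
  }
  # defaults
  config$discount_rate <- config$discount_rate %||% 0
  config$cohorts <- config$cohorts %||%
    lapply(default_cohorts(), function(x) list(label = x$label, size = x$size))
  config$prevalence_counts <- config$prevalence_counts %||% {
    m <- REFERENCE_CONDITION_COUNTS
    stats::setNames(lapply(CONDITIONS, function(cn) as.integer(m[cn, ])),
                    CONDITIONS)
  }

  ef <- config$effect
  if (is.null(ef$or) || ef$or <= 0) {
    stop_input("configuration error at 'effect.or': must be a positive number")
  }
  ef$ci_low <- ef$ci_low %||% ef$or
  ef$ci_high <- ef$ci_high %||% ef$or
  if (!(ef$ci_low <= ef$or && ef$or <= ef$ci_high)) {
    stop_input("configuration error at 'effect': need ci_low <= or <= ci_high")
  }
  config$effect <- ef

  bs <- unlist(config$baseline_states)[STATE_LEVELS]
  if (any(is.na(bs)) || any(bs < 0) || sum(bs) <= 0) {
    stop_input("configuration error at 'baseline_states': need non-negative ",
               "Q1..Q4 with positive total")
  }

  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    if (is.null(sc$name)) {
      stop_input("configuration error at 'scenarios.", i, ".name': missing")
    }
    f <- sc$exposed_fraction
    if (is.null(f) || f < 0 || f > 1) {
      stop_input("configuration error at 'scenarios.", i,
                 ".exposed_fraction': must lie in [0, 1]")
    }
    config$scenarios[[i]]$extra_traumas <- sc$extra_traumas %||% 1L
  }

  mk <- config$markov
  horizons <- mk$horizons %||% c(5L, 10L)
  if (any(horizons < 1) || any(horizons != round(horizons))) {
    stop_input("configuration error at 'markov.horizons': positive integers required")
  }
  config$markov$horizons <- as.integer(horizons)
  tmat <- do.call(rbind, mk$transition_matrix)
  tryCatch(
    transition_model(tmat, isTRUE(mk$progression_only %||% TRUE)),
    error = function(e) {
      stop_input("configuration error at 'markov.transition_matrix': ",
                 conditionMessage(e))
    }
  )
  if (is.null(mk$start_age)) stop_input("configuration error at 'markov.start_age': missing")

  mt <- config$mortality
  if (length(mt$ages) != length(mt$rates)) {
    stop_input("configuration error at 'mortality': ages and rates must align")
  }
  if (any(mt$rates < 0 | mt$rates > 1)) {
    stop_input("configuration error at 'mortality.rates': probabilities required")
  }

  check_costs_nonneg(config$costs, "costs")

  if (config$discount_rate < 0) {
    stop_input("configuration error at 'discount_rate': must be >= 0")
  }
  for (i in seq_along(config$cohorts)) {
    sz <- config$cohorts[[i]]$size
    if (is.null(sz) || !is_count(sz) || sz < 1) {
      stop_input("configuration error at 'cohorts.", i,
                 ".size': integer >= 1 required")
    }
  }
  if (!is.null(config$dsa)) {
    for (i in seq_along(config$dsa$ranges)) {
      r <- config$dsa$ranges[[i]]
      if (is.null(r$path) || is.null(r$low) || is.null(r$high)) {
        stop_input("configuration error at 'dsa.ranges.", i,
                   "': need path, low, high")
      }
    }
  }
  structure(config, class = c("model_config", "list"),
            metadata = list(source = source,
                            provenance = config$provenance,
                            package_version = as.character(
                              utils::packageVersion("traumacost"))))
}

# recursive non-negativity check over a nested cost block; errors name the
# offending dot-path
check_costs_nonneg <- function(node, path) {
  if (is.list(node)) {
    for (k in names(node)) {
      check_costs_nonneg(node[[k]], paste(path, k, sep = "."))
    }
  } else if (is.numeric(node) && any(node < 0)) {
    stop_input("configuration error at '", path, "': costs must be >= 0")
  }
  invisible(TRUE)
}

# --- constructors from a validated configuration ---------------------------

baseline_from_config <- function(config) {
  counts <- unlist(config$baseline_states)[STATE_LEVELS]
  severity_distribution(counts / sum(counts))
}

effect_from_config <- function(config) {
  trauma_effect(config$effect$or, config$effect$ci_low, config$effect$ci_high)
}

scenarios_from_config <- function(config) {
  lapply(config$scenarios, function(sc) {
    policy_scenario(sc$name, sc$exposed_fraction, sc$extra_traumas %||% 1L)
  })
}

transition_from_config <- function(config) {
  transition_model(do.call(rbind, config$markov$transition_matrix),
                   isTRUE(config$markov$progression_only %||% TRUE))
}

mortality_from_config <- function(config) {
  mortality_table(config$mortality$ages, config$mortality$rates)
}

prevalence_from_config <- function(config) {
  counts <- do.call(rbind, config$prevalence_counts[CONDITIONS])
  state_n <- unlist(config$baseline_states)[STATE_LEVELS]
  prev <- sweep(counts, 2L, state_n, "/")
  dimnames(prev) <- list(CONDITIONS, STATE_LEVELS)
  prev
}

costs_from_config <- function(config) {
  cc <- config$costs
  cond <- do.call(rbind, lapply(CONDITIONS, function(cn) {
    unlist(cc$conditions[[cn]])[c("direct", "indirect")]
  }))
  dimnames(cond) <- list(CONDITIONS, c("direct", "indirect"))
  cost_inputs(
    base_no_problems = unlist(cc$base_no_problems),
    base_behavior_problems = unlist(cc$base_behavior_problems),
    condition_costs = cond,
    prevalence = prevalence_from_config(config),
    include_q1_conditions = isTRUE(cc$include_q1_conditions),
    currency_note = config$meta$currency %||% "2018 USD"
  )
}

spec_from_config <- function(config) {
  ch <- config$cohort %||% list()
  counts <- unlist(config$baseline_states)[STATE_LEVELS]
  cohort_spec(
    n = ch$n %||% 458L,
    age_mean = ch$age_mean %||% 13, age_sd = ch$age_sd %||% 4,
    prop_male = ch$prop_male %||% 0.430,
    trauma_mean = ch$trauma_mean %||% 3.6, trauma_sd = ch$trauma_sd %||% 2.3,
    trauma_max = ch$trauma_max %||% 20L,
    beta_trauma = log(ch$or_per_trauma %||% config$effect$or),
    beta_age = ch$beta_age %||% 0, beta_sex = ch$beta_sex %||% 0,
    target_shares = as.numeric(counts) / sum(counts),
    prevalence_by_state = prevalence_from_config(config),
    seed = ch$seed %||% 20180401L
  )
}
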