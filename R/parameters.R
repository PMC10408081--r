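#' @keywords internal
"_PACKAGE"

STRATEGIES <- c("FOLFOX", "FOLFIRI", "CETUX_FOLFOX", "CETUX_FOLFIRI")
HEALTH_STATES <- c("STABLE", "PROGRESSIVE", "DEAD")
PARAM_ROLES <- c(
  "transition_probability", "cost", "utility", "relative_risk", "discount_rate"
)
COST_COMPONENTS <- c("direct_medical", "direct_nonmedical", "indirect", "drug")
PERSPECTIVES <- c("societal", "healthcare", "payer")

#' Path to the packaged default model configuration
#'
#' The packaged configuration carries the full published input table for the
#' four first-line strategies (time-banded transition probabilities, state
#' costs in 2023 IDR, utilities, discount rates and network-meta-analysis
#' relative risks) together with the default model settings.
#'
#' @return Path to the YAML file inside the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_model.yaml", package = "cetuxcea",
    mustWork = TRUE
  )
}

#' Load a full model configuration
#'
#' Reads a YAML or JSON configuration with sections `parameters`, `schedule`,
#' `strategies` and `settings`, validates the parameter table, and returns a
#' `model_config` object consumed by [run_cohort()], [run_psa()] and
#' [run_full_analysis()].
#'
#' @param config_source `NULL` for the packaged default, a path to a YAML or
#'   JSON file, or an already-parsed list with the same structure.
#' @return A list of class `model_config` with elements `parameters`
#'   (a validated `parameter_table` data frame), `settings`, `schedule`,
#'   `strategies`, `progressive_costs`, `capped_drugs`, `rr_death`.
#' @export
load_model_config <- function(config_source = NULL) {
  if (is.null(config_source)) config_source <- default_config_path()
  raw <- if (is.character(config_source)) {
    if (!file.exists(config_source)) stop("config file not found: ", config_source)
    if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config_source)
    }
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be NULL, a file path, or a list")
  }
  for (section in c("parameters", "settings", "strategies")) {
    if (is.null(raw[[section]])) stop("config is missing section '", section, "'")
  }
  cfg <- raw
  cfg$parameters <- validate_parameter_table(params_to_df(raw$parameters))
  cfg$settings <- validate_settings(raw$settings)
  class(cfg) <- "model_config"
  cfg
}

#' Load and validate the model parameter table
#'
#' @inheritParams load_model_config
#' @return A data frame of class `parameter_table` with one row per input
#'   parameter and columns `name`, `mean`, `se`, `distribution`, `role`,
#'   `strategy`, `from_state`, `to_state`, `band_start`, `band_end`,
#'   `component`.
#' @examples
#' tab <- load_parameter_table()
#' tab[tab$name == "U_stable", c("mean", "se", "distribution")]
#' @export
load_parameter_table <- function(config_source = NULL) {
  load_model_config(config_source)$parameters
}

params_to_df <- function(plist) {
  if (is.data.frame(plist)) {
    df <- plist
  } else {
    req <- c("name", "mean", "se", "distribution", "role")
    rows <- lapply(seq_along(plist), function(i) {
      rec <- plist[[i]]
      missing <- setdiff(req, names(rec))
      if (length(missing) > 0) {
        stop(sprintf(
          "parameter record %d (%s) is missing field(s): %s",
          i, if (is.null(rec$name)) "<unnamed>" else rec$name,
          paste(missing, collapse = ", ")
        ))
      }
      data.frame(
        name = rec$name, mean = as.numeric(rec$mean), se = as.numeric(rec$se),
        distribution = rec$distribution, role = rec$role,
        strategy = rec$strategy %||% "ALL",
        from_state = rec$from_state %||% NA_character_,
        to_state = rec$to_state %||% NA_character_,
        band_start = as.integer(rec$band_start %||% NA),
        band_end = as.integer(rec$band_end %||% NA),
        component = rec$component %||% NA_character_,
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
  }
  for (col in c("strategy", "from_state", "to_state", "component")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  }
  for (col in c("band_start", "band_end")) {
    if (is.null(df[[col]])) df[[col]] <- NA_integer_
  }
  df$strategy[is.na(df$strategy)] <- "ALL"
  df
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_parameter_table <- function(df) {
  dup <- df$name[duplicated(df$name)]
  if (length(dup) > 0) {
    stop("duplicate parameter name(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_role <- !df$role %in% PARAM_ROLES
  if (any(bad_role)) {
    stop(
      "unknown role for parameter(s): ",
      paste(df$name[bad_role], collapse = ", ")
    )
  }
  bad_strat <- !df$strategy %in% c(STRATEGIES, "ALL")
  if (any(bad_strat)) {
    stop(
      "unknown strategy tag for parameter(s): ",
      paste(df$name[bad_strat], collapse = ", ")
    )
  }
  if (any(!is.finite(df$mean))) {
    stop("non-finite mean for: ", paste(df$name[!is.finite(df$mean)], collapse = ", "))
  }
  if (any(!is.finite(df$se) | df$se < 0)) {
    stop("se must be finite and >= 0; offending: ",
      paste(df$name[!is.finite(df$se) | df$se < 0], collapse = ", "))
  }
  check <- function(sel, ok, msg) {
    bad <- sel & !ok
    if (any(bad)) stop(msg, ": ", paste(df$name[bad], collapse = ", "))
  }
  prob_like <- df$role %in% c("transition_probability", "utility")
  check(prob_like, df$distribution == "beta",
    "transition probabilities and utilities must use a beta distribution")
  check(prob_like, df$mean >= 0 & df$mean <= 1,
    "probability/utility mean outside [0, 1]")
  check(df$role == "cost", df$distribution == "gamma",
    "costs must use a gamma distribution")
  check(df$role == "cost", df$mean >= 0, "negative cost mean")
  check(df$role == "relative_risk", df$distribution == "lognormal",
    "relative risks must use a lognormal distribution")
  check(df$role == "relative_risk", df$mean > 0, "non-positive relative risk")
  check(df$role == "discount_rate", df$distribution == "fixed",
    "discount rates must be fixed")
  validate_bands(df)
  class(df) <- c("parameter_table", "data.frame")
  df
}

# bands for one (strategy, from_state, to_state) triple must be contiguous
# and non-overlapping, starting at month 1
validate_bands <- function(df) {
  tp <- df[df$role == "transition_probability", , drop = FALSE]
  if (nrow(tp) == 0) return(invisible(TRUE))
  if (any(is.na(tp$band_start) | is.na(tp$band_end))) {
    stop("transition probabilities must carry band_start/band_end: ",
      paste(tp$name[is.na(tp$band_start) | is.na(tp$band_end)], collapse = ", "))
  }
  if (any(tp$band_start < 1 | tp$band_end < tp$band_start)) {
    stop("invalid band bounds for: ",
      paste(tp$name[tp$band_start < 1 | tp$band_end < tp$band_start], collapse = ", "))
  }
  key <- paste(tp$strategy, tp$from_state, tp$to_state)
  for (k in unique(key)) {
    b <- tp[key == k, , drop = FALSE]
    b <- b[order(b$band_start), , drop = FALSE]
    if (b$band_start[1] != 1) {
      stop("bands for ", k, " must start at month 1")
    }
    if (nrow(b) > 1 && any(b$band_start[-1] != b$band_end[-nrow(b)] + 1)) {
      stop("bands for ", k, " are not contiguous/non-overlapping")
    }
  }
  invisible(TRUE)
}

validate_settings <- function(s) {
  defaults <- list(
    cycle_length_months = 1L, horizon_years = 30,
    extinction_threshold = 1e-6,
    discount_cost = 0.03, discount_outcome = 0.03,
    half_cycle_correction = TRUE, perspective = "societal",
    cetuximab_cost_duration_months = 12L, cost_period_months = 1L,
    cpi_factor = 1, progressive_death_mode = "pooled",
    pooled_progressive_death_strategy = "FOLFOX",
    extension_policy = "hold_last", reference_strategy = "FOLFIRI",
    threshold = 215e6, threshold_label = "3xGDP", threshold_1gdp = 215e6 / 3
  )
  s <- utils::modifyList(defaults, s[!vapply(s, is.null, logical(1))])
  if (!s$cycle_length_months %in% c(1, 3)) {
    stop("cycle_length_months must be 1 or 3")
  }
  if (s$horizon_years <= 0) stop("horizon_years must be > 0")
  if (s$discount_cost < 0 || s$discount_outcome < 0) {
    stop("discount rates must be >= 0")
  }
  s$perspective <- match.arg(s$perspective, PERSPECTIVES)
  s$progressive_death_mode <- match.arg(
    s$progressive_death_mode, c("pooled", "verbatim", "rr_adjusted")
  )
  s$extension_policy <- match.arg(s$extension_policy, c("hold_last", "absorb"))
  s
}

#' Convert a probability between period lengths
#'
#' Constant-rate conversion: a probability `p` referring to a period of
#' `period_from_months` is converted to `period_to_months` as
#' `1 - (1 - p)^(period_to/period_from)`. This is the standard
#' rate-to-probability translation used to move the published interval
#' probabilities onto the model's cycle length.
#'
#' @param p Probability in `[0, 1]` (vectorized).
#' @param period_from_months,period_to_months Period lengths in months, > 0.
#' @return Converted probability of the same length as `p`.
#' @examples
#' rescale_probability(0.005, 12, 3) # yearly risk to a quarter
#' @export
rescale_probability <- function(p, period_from_months, period_to_months) {
  if (any(period_from_months <= 0) || any(period_to_months <= 0)) {
    stop("period lengths must be > 0")
  }
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  if (any(p == 1) && any(period_to_months < period_from_months)) {
    warning("p = 1 over a shorter period is undefined under a constant rate; returning 1")
  }
  1 - (1 - p)^(period_to_months / period_from_months)
}

#' Adjust a probability by a relative risk
#'
#' Multiplicative on the probability scale, clipped at 1 (with a warning)
#' when the product exceeds 1.
#'
#' @param p Baseline probability in `[0, 1]` (vectorized).
#' @param rr Relative risk, > 0.
#' @return `min(p * rr, 1)`.
#' @examples
#' adjust_probability_by_rr(0.023, 0.948)
#' @export
adjust_probability_by_rr <- function(p, rr) {
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  if (any(rr <= 0)) stop("relative risk must be > 0")
  out <- p * rr
  if (any(out > 1)) {
    warning(sprintf("%d probability value(s) clipped to 1 after RR adjustment",
      sum(out > 1)))
    out <- pmin(out, 1)
  }
  out
}

#' Re-base a cost with a consumer-price-index factor
#'
#' The packaged costs are already expressed in 2023 IDR, so the default
#' factor is 1; the hook exists for re-basing to another price year.
#'
#' @param cost Cost amount(s), >= 0.
#' @param cpi_factor Multiplicative index factor, > 0.
#' @return `cost * cpi_factor`.
#' @export
inflate_cost <- function(cost, cpi_factor) {
  if (any(cost < 0)) stop("cost must be >= 0")
  if (any(cpi_factor <= 0)) stop("cpi_factor must be > 0")
  cost * cpi_factor
}

#' Export a parameter table to CSV
#'
#' @param table A `parameter_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_csv <- function(table, path) {
  stopifnot(inherits(table, "parameter_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Import a parameter table from CSV
#'
#' @param path CSV file written by [write_parameter_csv()] (columns `name`,
#'   `mean`, `se`, `distribution`, `role`, `strategy`, `from_state`,
#'   `to_state`, `band_start`, `band_end`, `component`).
#' @return A validated `parameter_table`.
#' @export
read_parameter_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_parameter_table(params_to_df(df))
}

# named mean lookup used throughout the engine
param_values <- function(table) {
  stats::setNames(table$mean, table$name)
}

#' Replace parameter means in a configuration
#'
#' Used by the sensitivity analyses to run the model on a sampled or
#' perturbed parameter set without re-validating distribution moments.
#'
#' @param config A `model_config`.
#' @param values Named numeric vector of replacement means (a subset of the
#'   table's parameter names).
#' @return The modified `model_config`.
#' @export
set_parameter_values <- function(config, values) {
  stopifnot(inherits(config, "model_config"))
  idx <- match(names(values), config$parameters$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(names(values)[is.na(idx)], collapse = ", "))
  }
  config$parameters$mean[idx] <- unname(values)
  config
}
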