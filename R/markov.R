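# Three-state cohort engine: STABLE (progression-free) -> PROGRESSIVE -> DEAD,
# with no remission path. Transitions are time-banded; each band's probability
# refers to a source period and is converted to the cycle length by the
# constant-rate formula. The cohort recursion is computed in closed vector
# form: stable occupancy is a cumulative product, and progressive occupancy
# s solved with a cumulative-sum identity on the survival product, which makes
# probabilistic sensitivity analysis cheap.

n_model_cycles <- function(settings) {
  as.integer(ceiling(settings$horizon_years * 12 / settings$cycle_length_months))
}

# band value lookup for a vector of months (band_start/band_end inclusive)
band_lookup <- function(months, band_start, band_end, values, extension_policy,
                        absorb_value) {
  ord <- order(band_start)
  band_start <- band_start[ord]; band_end <- band_end[ord]; values <- values[ord]
  idx <- findInterval(months, band_start)
  out <- values[pmax(idx, 1)]
  beyond <- months > band_end[length(band_end)]
  if (any(beyond) && extension_policy == "absorb") out[beyond] <- absorb_value
  out
}

# per-cycle transition probabilities for one strategy, converted to the
# cycle length; months are elapsed months at the START of each cycle
cycle_probabilities <- function(config, strategy, n_cycles = NULL) {
  s <- config$settings
  stopifnot(strategy %in% STRATEGIES)
  if (is.null(n_cycles)) n_cycles <- n_model_cycles(s)
  cl <- s$cycle_length_months
  m_start <- (seq_len(n_cycles) - 1) * cl + 1
  tab <- config$parameters
  tp <- tab[tab$role == "transition_probability", , drop = FALSE]
  sp <- config$schedule$source_period_months
  pick <- function(strat, from, to) {
    tp[tp$strategy == strat & tp$from_state == from & tp$to_state == to, , drop = FALSE]
  }
  ext <- s$extension_policy

  ss <- pick(strategy, "STABLE", "STABLE")
  if (nrow(ss) == 0) stop("no STABLE->STABLE schedule for strategy ", strategy)
  pss_src <- band_lookup(m_start, ss$band_start, ss$band_end, ss$mean, ext, 0)
  pss <- 1 - rescale_probability(1 - pss_src, sp$stable_stay %||% 3, cl)

  sd <- pick("ALL", "STABLE", "DEAD")
  psd_src <- band_lookup(m_start, sd$band_start, sd$band_end, sd$mean, ext, 1)
  psd <- rescale_probability(psd_src, sp$stable_death %||% 12, cl)

  pd_strategy <- switch(s$progressive_death_mode,
    pooled = s$pooled_progressive_death_strategy,
    verbatim = strategy,
    rr_adjusted = s$pooled_progressive_death_strategy
  )
  pd <- pick(pd_strategy, "PROGRESSIVE", "DEAD")
  ppd_src <- band_lookup(m_start, pd$band_start, pd$band_end, pd$mean, ext, 1)
  if (s$progressive_death_mode == "rr_adjusted" &&
    strategy != s$pooled_progressive_death_strategy) {
    rr_name <- config$rr_death[[strategy]]
    if (is.null(rr_name)) stop("no death relative risk mapped for ", strategy)
    rr <- tab$mean[tab$name == rr_name]
    ppd_src <- adjust_probability_by_rr(ppd_src, rr)
  }
  ppd <- rescale_probability(ppd_src, sp$progressive_death %||% 1, cl)

  # keep the stable row stochastic: progression gets what is left
  over <- pss + psd > 1
  if (any(over)) {
    warning(sprintf(
      "strategy %s: STABLE row renormalized in %d cycle(s) (pSS + pSD > 1)",
      strategy, sum(over)
    ))
    pss[over] <- 1 - psd[over]
  }
  list(
    pss = pss, psd = psd, ppd = ppd, psp = pmax(1 - pss - psd, 0),
    month_start = m_start, month_end = m_start + cl - 1
  )
}

#' Build the transition matrix for one cycle
#'
#' Returns the 3x3 row-stochastic matrix over the states STABLE,
#' PROGRESSIVE, DEAD for a given strategy and cycle. The STABLE row is
#' `(pSS, 1 - pSS - pSD, pSD)`, the PROGRESSIVE row `(0, 1 - pPD, pPD)`
#' and DEAD is absorbing. If `pSS + pSD > 1` the progression entry is
#' floored at zero and `pSS` renormalized, with a warning.
#'
#' @param strategy One of `"FOLFOX"`, `"FOLFIRI"`, `"CETUX_FOLFOX"`,
#'   `"CETUX_FOLFIRI"`.
#' @param cycle_index 1-based cycle number.
#' @param config A `model_config` from [load_model_config()].
#' @return A 3x3 matrix with dimnames over the health states.
#' @export
build_transition_matrix <- function(strategy, cycle_index, config) {
  if (cycle_index < 1) stop("cycle_index must be >= 1")
  probs <- cycle_probabilities(config, strategy, n_cycles = cycle_index)
  i <- cycle_index
  mat <- rbind(
    c(probs$pss[i], probs$psp[i], probs$psd[i]),
    c(0, 1 - probs$ppd[i], probs$ppd[i]),
    c(0, 0, 1)
  )
  dimnames(mat) <- list(HEALTH_STATES, HEALTH_STATES)
  mat
}

# monthly-equivalent cost rates per state and component for one strategy;
# returns function of cycle start months -> matrix n x 4 (per cycle, in IDR)
state_cost_rates <- function(config, strategy, month_start) {
  s <- config$settings
  tab <- config$parameters
  vals <- param_values(tab)
  cl <- s$cycle_length_months
  per_cycle <- cl / (s$cost_period_months %||% 1)
  comp_of <- stats::setNames(tab$component, tab$name)
  n <- length(month_start)
  stable <- matrix(0, n, length(COST_COMPONENTS),
    dimnames = list(NULL, COST_COMPONENTS)
  )
  prog <- stable
  strat_def <- config$strategies[[strategy]]
  if (is.null(strat_def)) stop("strategy ", strategy, " not defined in config")
  for (nm in unlist(strat_def$stable_costs)) {
    stable[, comp_of[[nm]]] <- stable[, comp_of[[nm]]] + vals[[nm]]
  }
  capped <- unlist(config$capped_drugs %||% list())
  for (nm in unlist(strat_def$drugs)) {
    amount <- rep(vals[[nm]], n)
    if (nm %in% capped) {
      amount[month_start > s$cetuximab_cost_duration_months] <- 0
    }
    stable[, "drug"] <- stable[, "drug"] + amount
  }
  for (nm in unlist(config$progressive_costs)) {
    prog[, comp_of[[nm]]] <- prog[, comp_of[[nm]]] + vals[[nm]]
  }
  cpi <- s$cpi_factor %||% 1
  list(
    stable = inflate_cost(stable * per_cycle, cpi),
    prog = inflate_cost(prog * per_cycle, cpi)
  )
}

#' Run the cohort model for one strategy
#'
#' Propagates a cohort starting in the progression-free (STABLE) state
#' through the three-state model until the horizon or cohort extinction,
#' accumulating per-cycle state occupancy and cost, life-year and QALY
#' increments, discounted and undiscounted. With
#' `settings$half_cycle_correction` the increments weight each cycle by the
#' average of its beginning and end occupancy (transitions treated as
#' mid-cycle events); otherwise beginning-of-cycle occupancy is used.
#'
#' @inheritParams build_transition_matrix
#' @param n_cycles Optional override of the number of cycles (defaults to
#'   the horizon in `config$settings`).
#' @return A data frame of class `markov_trace` with one row per cycle
#'   (plus the entry row, cycle 0): occupancy in the three states and
#'   per-cycle increments `ly`, `qaly`, `cost_<component>`, each also as
#'   `*_disc`.
#' @examples
#' cfg <- load_model_config()
#' tr <- run_cohort("FOLFOX", cfg)
#' sum(tr$ly_disc) # discounted life-years
#' @export
run_cohort <- function(strategy, config, n_cycles = NULL) {
  stopifnot(inherits(config, "model_config"))
  s <- config$settings
  probs <- cycle_probabilities(config, strategy, n_cycles)
  n <- length(probs$pss)
  cl <- s$cycle_length_months

  stab <- cumprod(probs$pss)
  surv_p <- cumprod(1 - probs$ppd)
  stab_prev <- c(1, stab[-n])
  inflow <- stab_prev * probs$psp
  prog <- surv_p * cumsum(inflow / surv_p)
  dead <- 1 - stab - prog

  # cohort extinction stop: drop cycles after living occupancy falls below
  # the threshold (increments there are numerically negligible)
  alive <- stab + prog
  cut <- which(alive < (s$extinction_threshold %||% 1e-6))
  if (length(cut) > 0 && cut[1] < n) {
    keep <- seq_len(cut[1])
    n <- cut[1]
    probs <- lapply(probs, `[`, keep)
    stab <- stab[keep]; prog <- prog[keep]; dead <- dead[keep]
    stab_prev <- stab_prev[keep]
  }
  prog_prev <- c(0, prog[-n])

  if (isTRUE(s$half_cycle_correction)) {
    w_stab <- (stab_prev + stab) / 2
    w_prog <- (prog_prev + prog) / 2
  } else {
    w_stab <- stab_prev
    w_prog <- prog_prev
  }

  rates <- state_cost_rates(config, strategy, probs$month_start)
  vals <- param_values(config$parameters)
  u_s <- vals[["U_stable"]]
  u_p <- vals[["U_progressive"]]
  cycle_years <- cl / 12
  m_end <- probs$month_end
  disc_c <- (1 + vals[["D_cost"]])^(-(m_end / 12))
  disc_o <- (1 + vals[["D_outcome"]])^(-(m_end / 12))

  ly <- (w_stab + w_prog) * cycle_years
  qaly <- (u_s * w_stab + u_p * w_prog) * cycle_years
  cost <- rates$stable * w_stab + rates$prog * w_prog

  trace <- data.frame(
    cycle = 0:n,
    month = c(0, m_end),
    occ_stable = c(1, stab),
    occ_progressive = c(0, prog),
    occ_dead = c(0, dead),
    ly = c(0, ly),
    qaly = c(0, qaly),
    ly_disc = c(0, ly * disc_o),
    qaly_disc = c(0, qaly * disc_o)
  )
  for (comp in COST_COMPONENTS) {
    trace[[paste0("cost_", comp)]] <- c(0, cost[, comp])
    trace[[paste0("cost_", comp, "_disc")]] <- c(0, cost[, comp] * disc_c)
  }
  structure(trace,
    class = c("markov_trace", "data.frame"),
    strategy = strategy,
    settings = s,
    half_cycle_corrected = isTRUE(s$half_cycle_correction),
    rates = list(
      stable = rates$stable, prog = rates$prog, u_stable = u_s,
      u_progressive = u_p, disc_cost = disc_c, disc_outcome = disc_o,
      cycle_years = cycle_years
    )
  )
}

#' Re-weight a trace with the half-cycle correction
#'
#' Recomputes every per-cycle increment of an uncorrected trace using the
#' average of beginning- and end-of-cycle occupancy (equivalently, half
#' weight on the first and last observation of a life-table sum). A trace
#' already computed with the correction is returned unchanged.
#'
#' @param trace A `markov_trace` from [run_cohort()].
#' @return The corrected `markov_trace`.
#' @export
apply_half_cycle_correction <- function(trace) {
  stopifnot(inherits(trace, "markov_trace"))
  if (isTRUE(attr(trace, "half_cycle_corrected"))) {
    return(trace)
  }
  r <- attr(trace, "rates")
  n <- nrow(trace) - 1
  stopifnot(n >= 1)
  stab <- trace$occ_stable
  prog <- trace$occ_progressive
  w_stab <- (stab[-(n + 1)] + stab[-1]) / 2
  w_prog <- (prog[-(n + 1)] + prog[-1]) / 2
  ly <- (w_stab + w_prog) * r$cycle_years
  qaly <- (r$u_stable * w_stab + r$u_progressive * w_prog) * r$cycle_years
  cost <- r$stable * w_stab + r$prog * w_prog
  trace$ly <- c(0, ly)
  trace$qaly <- c(0, qaly)
  trace$ly_disc <- c(0, ly * r$disc_outcome)
  trace$qaly_disc <- c(0, qaly * r$disc_outcome)
  for (comp in COST_COMPONENTS) {
    trace[[paste0("cost_", comp)]] <- c(0, cost[, comp])
    trace[[paste0("cost_", comp, "_disc")]] <- c(0, cost[, comp] * r$disc_cost)
  }
  attr(trace, "half_cycle_corrected") <- TRUE
  s <- attr(trace, "settings")
  s$half_cycle_correction <- TRUE
  attr(trace, "settings") <- s
  trace
}

perspective_components <- function(perspective) {
  perspective <- match.arg(perspective, PERSPECTIVES)
  switch(perspective,
    societal = COST_COMPONENTS,
    healthcare = c("direct_medical", "drug"),
    payer = c("direct_medical", "drug")
  )
}

#' Sum a trace into lifetime outcomes for one strategy
#'
#' @param trace A `markov_trace`.
#' @param perspective `"societal"` (all components), `"healthcare"` or
#'   `"payer"` (direct medical + drug).
#' @return One-row data frame with the strategy's total discounted and
#'   undiscounted cost (plus the discounted component breakdown),
#'   life-years and QALYs.
#' @export
accumulate_outcomes <- function(trace, perspective = "societal") {
  stopifnot(inherits(trace, "markov_trace"))
  comps <- perspective_components(perspective)
  cost <- sum(vapply(comps, function(k) sum(trace[[paste0("cost_", k)]]), 0))
  cost_disc <- sum(vapply(
    comps, function(k) sum(trace[[paste0("cost_", k, "_disc")]]), 0
  ))
  out <- data.frame(
    strategy = attr(trace, "strategy"),
    perspective = perspective,
    cost = cost_disc,
    ly = sum(trace$ly_disc),
    qaly = sum(trace$qaly_disc),
    cost_undisc = cost,
    ly_undisc = sum(trace$ly),
    qaly_undisc = sum(trace$qaly),
    stringsAsFactors = FALSE
  )
  for (k in COST_COMPONENTS) {
    out[[paste0("cost_", k)]] <-
      if (k %in% comps) sum(trace[[paste0("cost_", k, "_disc")]]) else 0
  }
  out
}

#' Base-case outcomes for a set of strategies
#'
#' Runs [run_cohort()] and [accumulate_outcomes()] for each strategy.
#'
#' @param config A `model_config`.
#' @param strategies Character vector of strategies (default: all four).
#' @param perspective Costing perspective; defaults to the config setting.
#' @return Data frame with one row per strategy.
#' @examples
#' cfg <- load_model_config()
#' run_base_case(cfg)[, c("strategy", "cost", "ly", "qaly")]
#' @export
run_base_case <- function(config, strategies = STRATEGIES,
                          perspective = config$settings$perspective) {
  do.call(rbind, lapply(strategies, function(st) {
    accumulate_outcomes(run_cohort(st, config), perspective)
  }))
}
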