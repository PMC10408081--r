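# shared fixtures: the packaged configuration is loaded once per test run,
# and a minimal single-strategy configuration is built in code for
# degenerate-case tests

packaged_config <- load_model_config()

# minimal model: one strategy, flat probabilities, optional zero costs.
# pss/psd/ppd are per-cycle (source periods = cycle length)
toy_config <- function(pss = 0.9, psd = 0.02, ppd = 0.05,
                       stable_cost = 0, prog_cost = 0, drug_cost = 0,
                       u_stable = 1, u_progressive = 1,
                       discount = 0, horizon_years = 10,
                       cycle_length_months = 1,
                       half_cycle_correction = TRUE,
                       extinction_threshold = 0) {
  par <- list(
    list(
      name = "tpStoS_toy_1", mean = pss, se = 0, distribution = "beta",
      role = "transition_probability", strategy = "FOLFOX",
      from_state = "STABLE", to_state = "STABLE", band_start = 1L,
      band_end = 1200L
    ),
    list(
      name = "tpStoD_toy_1", mean = psd, se = 0, distribution = "beta",
      role = "transition_probability", strategy = "ALL",
      from_state = "STABLE", to_state = "DEAD", band_start = 1L,
      band_end = 1200L
    ),
    list(
      name = "tpPtoD_toy_1", mean = ppd, se = 0, distribution = "beta",
      role = "transition_probability", strategy = "FOLFOX",
      from_state = "PROGRESSIVE", to_state = "DEAD", band_start = 1L,
      band_end = 1200L
    ),
    list(
      name = "Cost_toy_stable", mean = stable_cost, se = 0,
      distribution = "gamma", role = "cost", strategy = "FOLFOX",
      from_state = "STABLE", component = "direct_medical"
    ),
    list(
      name = "Cost_toy_prog", mean = prog_cost, se = 0,
      distribution = "gamma", role = "cost", strategy = "ALL",
      from_state = "PROGRESSIVE", component = "direct_medical"
    ),
    list(
      name = "Drug_toy", mean = drug_cost, se = 0, distribution = "gamma",
      role = "cost", strategy = "ALL", from_state = "STABLE",
      component = "drug"
    ),
    list(
      name = "U_stable", mean = u_stable, se = 0, distribution = "beta",
      role = "utility", from_state = "STABLE"
    ),
    list(
      name = "U_progressive", mean = u_progressive, se = 0,
      distribution = "beta", role = "utility", from_state = "PROGRESSIVE"
    ),
    list(
      name = "D_cost", mean = discount, se = 0, distribution = "fixed",
      role = "discount_rate"
    ),
    list(
      name = "D_outcome", mean = discount, se = 0, distribution = "fixed",
      role = "discount_rate"
    )
  )
  load_model_config(list(
    settings = list(
      cycle_length_months = cycle_length_months,
      horizon_years = horizon_years,
      extinction_threshold = extinction_threshold,
      discount_cost = discount, discount_outcome = discount,
      half_cycle_correction = half_cycle_correction,
      progressive_death_mode = "verbatim",
      cetuximab_cost_duration_months = 12L
    ),
    schedule = list(source_period_months = list(
      stable_stay = cycle_length_months,
      stable_death = cycle_length_months,
      progressive_death = cycle_length_months
    )),
    strategies = list(FOLFOX = list(
      drugs = list("Drug_toy"),
      stable_costs = list("Cost_toy_stable")
    )),
    progressive_costs = list("Cost_toy_prog"),
    capped_drugs = list(),
    parameters = par
  ))
}

# raw list form of the packaged config, for building modified variants
packaged_config_raw <- yaml::read_yaml(default_config_path())
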