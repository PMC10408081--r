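test_that("EQ-5D valuation anchors at full health and sums decrements", {
  vs <- synthetic_value_set()
  expect_equal(value_eq5d_profile(c(1, 1, 1, 1, 1), vs), 1.0)
  zero_vs <- vs * 0
  expect_equal(value_eq5d_profile(c(4, 2, 5, 3, 1), zero_vs), 1.0)
  worst <- value_eq5d_profile(c(5, 5, 5, 5, 5), vs)
  expect_equal(worst, 1 - sum(vs[, "level5"]), tolerance = 1e-12)
  expect_lt(worst, 0) # worst state below zero, as in published value sets
  expect_error(value_eq5d_profile(c(0, 1, 1, 1, 1), vs), "1-5")
  expect_error(value_eq5d_profile(c(1, 1, 6, 1, 1), vs), "1-5")
})

test_that("EQ-5D generators recover the published state utilities", {
  stable <- generate_eq5d_records(1e4, "STABLE", seed = 3)
  expect_equal(mean(stable$utility), 0.798, tolerance = 0.01 / 0.798)
  prog <- generate_eq5d_records(1e4, "PROGRESSIVE", seed = 3)
  expect_lt(abs(mean(prog$utility) - 0.443), 0.02)
  # levels are valid and valuations consistent with the value set
  vs <- synthetic_value_set()
  lv <- as.matrix(stable[1:50, 3:7])
  expect_true(all(lv >= 1 & lv <= 5))
  for (i in 1:50) {
    expect_equal(stable$utility[i], value_eq5d_profile(lv[i, ], vs))
  }
})

test_that("EQ-5D generation is seed-deterministic and validates targets", {
  a <- generate_eq5d_records(50, "STABLE", seed = 42)
  b <- generate_eq5d_records(50, "STABLE", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_eq5d_records(50, "STABLE", seed = 43)))
  expect_error(
    generate_eq5d_records(10, "STABLE", target_mean = -2, target_sd = 0.1),
    "attainable"
  )
})

test_that("cost records hit the published component means at scale", {
  cr <- generate_cost_records(5000, "STABLE", packaged_config,
    strategy = "CETUX_FOLFIRI", seed = 4
  )
  mc_tol <- function(x) 4 * sd(x) / sqrt(length(x))
  dnm <- cr$travel + cr$accommodation
  expect_lt(abs(mean(dnm) - 5748519), mc_tol(dnm))
  expect_lt(abs(mean(cr$direct_medical) - 14448000), mc_tol(cr$direct_medical))
  ind <- cr$income_loss_patient + cr$income_loss_caregiver
  expect_lt(abs(mean(ind) - 6149008), mc_tol(ind))
  # travel is literally distance x visits x fuel price
  expect_equal(cr$travel, cr$distance_km * cr$visits * 10000, tolerance = 1e-12)
  expect_true(all(cr[, c(
    "direct_medical", "travel", "accommodation",
    "income_loss_patient", "income_loss_caregiver"
  )] >= 0))
})

test_that("an interview-sized sample is plausible and seed-deterministic", {
  cr <- generate_cost_records(22, "STABLE", packaged_config, seed = 6)
  expect_equal(nrow(cr), 22)
  dnm <- cr$travel + cr$accommodation
  # within wide sampling error of the published state mean at n = 22
  # (the published SE 397,365 is itself the SD of a 22-record mean)
  expect_lt(abs(mean(dnm) - 5748519), 6 * 397365)
  expect_identical(
    cr, generate_cost_records(22, "STABLE", packaged_config, seed = 6)
  )
})

test_that("wage-missing records are imputed at the provincial minimum wage", {
  cr <- generate_cost_records(400, "STABLE", packaged_config,
    seed = 9,
    options = list(p_wage_missing = 0.5, min_wage_daily = 150000, cv_days = 0)
  )
  expect_gt(sum(cr$wage_missing), 0)
  missing <- cr[cr$wage_missing, ]
  # with constant days lost, imputed income is exactly days x minimum wage
  total <- missing$income_loss_patient + missing$income_loss_caregiver
  expect_equal(total, rep(8 * 150000, nrow(missing)), tolerance = 1e-9)
})

test_that("zero-variance settings produce identical records", {
  cfg <- packaged_config
  cfg$parameters$se[cfg$parameters$role == "cost"] <- 0
  cr <- generate_cost_records(10, "STABLE", cfg,
    seed = 2,
    options = list(
      cv_distance = 0, cv_accommodation = 0, cv_days = 0, cv_wage = 0,
      visit_mean = 1, p_wage_missing = 0
    )
  )
  for (col in c(
    "direct_medical", "travel", "accommodation",
    "income_loss_patient", "income_loss_caregiver"
  )) {
    expect_equal(cr[[col]], rep(cr[[col]][1], 10), tolerance = 1e-12)
  }
})

test_that("record summaries return valid parameter entries", {
  cr_s <- generate_cost_records(3000, "STABLE", packaged_config,
    strategy = "CETUX_FOLFIRI", seed = 10
  )
  cr_p <- generate_cost_records(3000, "PROGRESSIVE", packaged_config, seed = 11)
  pars <- summarize_records_to_params(rbind(cr_s, cr_p), "CETUX_FOLFIRI")
  expect_setequal(pars$name, c(
    "CostDM_S_cetuxfolfiri", "CostDnM_S_cetuxfolfiri", "CostIn_S_cetuxfolfiri",
    "CostDM_P_progressive", "CostDnM_P_progressive", "CostIn_P_progressive"
  ))
  # recovers the generating means within 2 standard errors
  tab <- packaged_config$parameters
  for (nm in pars$name) {
    target <- tab$mean[tab$name == nm]
    got <- pars[pars$name == nm, ]
    expect_lt(abs(got$mean - target), 4 * got$se * sqrt(3000 / 22))
  }
  # entries drop into the configuration schema unmodified
  raw <- packaged_config_raw
  keep <- !vapply(
    raw$parameters, function(p) p$name %in% pars$name, logical(1)
  )
  raw$parameters <- c(
    raw$parameters[keep],
    lapply(seq_len(nrow(pars)), function(i) as.list(pars[i, ]))
  )
  cfg2 <- load_model_config(raw)
  expect_equal(nrow(cfg2$parameters), 73)
})

test_that("summaries refuse single-record states and constants have zero SE", {
  one <- generate_cost_records(1, "STABLE", packaged_config, seed = 1)
  expect_error(summarize_records_to_params(one), ">= 2 records")
  cfg <- packaged_config
  cfg$parameters$se[cfg$parameters$role == "cost"] <- 0
  cr <- generate_cost_records(8, "STABLE", cfg,
    seed = 2,
    options = list(
      cv_distance = 0, cv_accommodation = 0, cv_days = 0, cv_wage = 0,
      visit_mean = 1, p_wage_missing = 0
    )
  )
  pars <- summarize_records_to_params(cr)
  expect_equal(pars$se, rep(0, nrow(pars)), tolerance = 1e-9)
})

test_that("synthetic trial tables are seed-deterministic and validated", {
  t1 <- generate_nma_trials(c(A = 1.5), 0.3, 100, seed = 5)
  expect_identical(t1, generate_nma_trials(c(A = 1.5), 0.3, 100, seed = 5))
  expect_error(generate_nma_trials(c(A = 4), 0.3, 100), "infeasible")
  expect_error(generate_nma_trials(c(A = 1.2), 0, 100), "\\(0,1\\)")
  expect_true(all(t1$events <= t1$n))
  prov <- attr(t1, "provenance")
  expect_equal(prov$seed, 5L)
})

test_that("synthetic interview pipeline closes back to the packaged model", {
  # parameters re-estimated from large synthetic interview datasets drive
  # the Markov model to the same place as the packaged table
  n <- 4000
  raw <- packaged_config_raw
  all_pars <- list()
  for (strat in c("FOLFOX", "FOLFIRI", "CETUX_FOLFOX", "CETUX_FOLFIRI")) {
    cr <- generate_cost_records(n, "STABLE", packaged_config,
      strategy = strat, seed = 100 + match(strat, c(
        "FOLFOX", "FOLFIRI", "CETUX_FOLFOX", "CETUX_FOLFIRI"
      ))
    )
    all_pars[[strat]] <- summarize_records_to_params(cr, strat)
  }
  cr_p <- generate_cost_records(n, "PROGRESSIVE", packaged_config, seed = 200)
  all_pars$prog <- summarize_records_to_params(cr_p)
  pars <- do.call(rbind, all_pars)
  pars <- pars[!duplicated(pars$name), ]
  eq_s <- generate_eq5d_records(n, "STABLE", seed = 300)
  eq_p <- generate_eq5d_records(n, "PROGRESSIVE", seed = 301)
  util <- data.frame(
    name = c("U_stable", "U_progressive"),
    mean = c(mean(eq_s$utility), mean(eq_p$utility)),
    se = c(sd(eq_s$utility), sd(eq_p$utility)) / sqrt(n)
  )
  replace <- c(pars$name, util$name)
  keep <- !vapply(raw$parameters, function(p) p$name %in% replace, logical(1))
  raw$parameters <- c(
    raw$parameters[keep],
    lapply(seq_len(nrow(pars)), function(i) as.list(pars[i, ])),
    list(
      list(
        name = "U_stable", mean = util$mean[1], se = util$se[1],
        distribution = "beta", role = "utility", from_state = "STABLE"
      ),
      list(
        name = "U_progressive", mean = util$mean[2], se = util$se[2],
        distribution = "beta", role = "utility", from_state = "PROGRESSIVE"
      )
    )
  )
  cfg_syn <- load_model_config(raw)
  bc_syn <- run_base_case(cfg_syn)
  bc_ref <- run_base_case(packaged_config)
  m <- merge(bc_syn, bc_ref, by = "strategy", suffixes = c("_syn", "_ref"))
  expect_equal(m$cost_syn, m$cost_ref, tolerance = 0.03)
  expect_equal(m$qaly_syn, m$qaly_ref, tolerance = 0.03)
  expect_equal(m$ly_syn, m$ly_ref, tolerance = 1e-9) # transitions untouched
})
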