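test_that("transition matrices are row-stochastic with an absorbing death state", {
  for (st in c("FOLFOX", "CETUX_FOLFIRI")) {
    for (cycle in c(1, 5, 13, 40, 200)) {
      m <- build_transition_matrix(st, cycle, packaged_config)
      expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      expect_equal(unname(m["DEAD", ]), c(0, 0, 1))
      expect_equal(m["PROGRESSIVE", "STABLE"], 0) # no remission path
    }
  }
  expect_error(build_transition_matrix("FOLFOX", 0, packaged_config), ">= 1")
})

test_that("band extension holds the last value beyond the evidence window", {
  m36 <- build_transition_matrix("FOLFOX", 36, packaged_config)
  m120 <- build_transition_matrix("FOLFOX", 120, packaged_config)
  expect_equal(m120["PROGRESSIVE", "DEAD"], m36["PROGRESSIVE", "DEAD"])
})

test_that("stable row is renormalized when pSS + pSD would exceed 1", {
  cfg <- toy_config(pss = 0.99, psd = 0.05)
  expect_warning(m <- build_transition_matrix("FOLFOX", 1, cfg), "renormalized")
  expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(m["STABLE", "PROGRESSIVE"], 0)
})

test_that("an immortal cohort accrues exactly the horizon in life-years", {
  cfg <- toy_config(pss = 1, psd = 0, ppd = 0, horizon_years = 30)
  tr <- run_cohort("FOLFOX", cfg)
  expect_equal(sum(tr$ly), 30, tolerance = 1e-9)
  expect_equal(sum(tr$qaly), sum(tr$ly)) # utility 1 everywhere
})

test_that("immediate absorption with half-cycle correction gives half a cycle", {
  cfg <- toy_config(pss = 0, psd = 1, horizon_years = 2)
  tr <- suppressWarnings(run_cohort("FOLFOX", cfg))
  expect_equal(sum(tr$ly), 0.5 / 12, tolerance = 1e-12)
})

test_that("half-cycle correction averages beginning and end occupancy", {
  raw <- packaged_config_raw
  raw$settings$half_cycle_correction <- FALSE
  cfg_nohcc <- load_model_config(raw)
  for (st in c("FOLFOX", "CETUX_FOLFOX")) {
    corrected <- apply_half_cycle_correction(run_cohort(st, cfg_nohcc))
    direct <- run_cohort(st, packaged_config)
    expect_equal(
      as.data.frame(corrected), as.data.frame(direct),
      tolerance = 1e-12
    )
    # a corrected trace is returned unchanged
    expect_equal(
      as.data.frame(apply_half_cycle_correction(direct)),
      as.data.frame(direct)
    )
  }
  # constant-occupancy cohort: correction changes nothing
  cfg_im <- toy_config(pss = 1, psd = 0, half_cycle_correction = FALSE)
  tr <- run_cohort("FOLFOX", cfg_im)
  expect_equal(sum(apply_half_cycle_correction(tr)$ly), sum(tr$ly))
})

test_that("the closed-form cohort recursion matches explicit matrix stepping", {
  # 400 cycles of left-multiplication with the per-cycle matrices is the
  # independent oracle for the vectorized engine, and carries the occupancy
  # conservation check
  raw <- packaged_config_raw
  raw$settings$horizon_years <- 400 / 12
  raw$settings$extinction_threshold <- 0
  cfg <- load_model_config(raw)
  for (st in c("FOLFOX", "CETUX_FOLFIRI")) {
    tr <- run_cohort(st, cfg)
    occ <- c(1, 0, 0)
    for (cycle in seq_len(nrow(tr) - 1)) {
      occ <- as.vector(occ %*% build_transition_matrix(st, cycle, cfg))
      expect_equal(sum(occ), 1, tolerance = 1e-9)
      expect_equal(
        occ,
        unlist(tr[cycle + 1, c("occ_stable", "occ_progressive", "occ_dead")],
          use.names = FALSE
        ),
        tolerance = 1e-9
      )
    }
  }
})

test_that("death occupancy is monotone and LY decreases in progressive mortality", {
  tr <- run_cohort("FOLFIRI", packaged_config)
  expect_true(all(diff(tr$occ_dead) >= -1e-15))

  base_ly <- sum(run_cohort("FOLFOX", packaged_config)$ly)
  for (nm in c("tpPtoD_folfox_2", "tpPtoD_folfox_6")) {
    up <- set_parameter_values(
      packaged_config,
      stats::setNames(
        packaged_config$parameters$mean[packaged_config$parameters$name == nm] + 0.01, nm
      )
    )
    expect_lt(sum(run_cohort("FOLFOX", up)$ly), base_ly)
  }
})

test_that("a 1e5-patient microsimulation reproduces the cohort trace", {
  cfg <- packaged_config
  tr <- run_cohort("FOLFOX", cfg)
  n_cycles <- nrow(tr) - 1
  n_pat <- 1e5
  set.seed(2024)
  counts <- c(n_pat, 0, 0)
  ly_micro <- 0
  max_z <- 0
  for (cycle in seq_len(n_cycles)) {
    m <- build_transition_matrix("FOLFOX", cycle, cfg)
    new <- numeric(3)
    for (s in 1:3) {
      if (counts[s] > 0) new <- new + as.vector(stats::rmultinom(1, counts[s], m[s, ]))
    }
    ly_micro <- ly_micro + (sum(counts[1:2]) + sum(new[1:2])) / 2
    counts <- new
    p <- unlist(tr[cycle + 1, c("occ_stable", "occ_progressive", "occ_dead")])
    se <- sqrt(pmax(p * (1 - p), 1e-12) / n_pat)
    max_z <- max(max_z, abs(counts / n_pat - p) / (se + 1 / n_pat))
  }
  expect_lt(max_z, 3) # within 3 binomial SE at every cycle and state
  ly_cohort <- sum(tr$ly)
  expect_lt(abs(ly_micro / n_pat / 12 - ly_cohort) / ly_cohort, 0.005)
})

test_that("discounting orders outcomes and never exceeds the undiscounted total", {
  ly <- sapply(c(0, 0.03, 0.05), function(r) {
    cfg <- set_parameter_values(packaged_config, c(D_outcome = r, D_cost = r))
    out <- accumulate_outcomes(run_cohort("FOLFOX", cfg))
    c(out$ly, out$cost)
  })
  expect_true(all(diff(ly[1, ]) < 0)) # LY strictly decreasing in the rate
  expect_true(all(diff(ly[2, ]) < 0))
  out <- accumulate_outcomes(run_cohort("CETUX_FOLFOX", packaged_config))
  expect_lte(out$cost, out$cost_undisc)
  expect_lte(out$ly, out$ly_undisc)
  expect_lte(out$qaly, out$ly) # utilities <= 1
})

test_that("perspectives nest: societal costs dominate healthcare costs", {
  for (st in STRATEGIES <- c("FOLFOX", "FOLFIRI", "CETUX_FOLFOX", "CETUX_FOLFIRI")) {
    tr <- run_cohort(st, packaged_config)
    soc <- accumulate_outcomes(tr, "societal")
    hc <- accumulate_outcomes(tr, "healthcare")
    expect_gte(soc$cost, hc$cost)
    expect_equal(soc$ly, hc$ly) # outcomes unaffected by costing perspective
  }
  expect_error(accumulate_outcomes(tr, "martian"))
})

test_that("zero discount and unit utilities make QALYs equal life-years", {
  cfg <- toy_config(pss = 0.8, psd = 0.01, ppd = 0.1, discount = 0)
  out <- accumulate_outcomes(run_cohort("FOLFOX", cfg))
  expect_equal(out$qaly, out$ly, tolerance = 1e-12)
  expect_equal(out$ly, out$ly_undisc)
})

test_that("cetuximab drug cost accrues only in the stable state, capped at 12 months", {
  tr <- run_cohort("CETUX_FOLFOX", packaged_config)
  mid_stable <- (tr$occ_stable[-nrow(tr)] + tr$occ_stable[-1]) / 2
  drug <- tr$cost_drug[-1]
  month <- tr$month[-1]
  chemo_monthly <- 13588228
  cetux_monthly <- 42673806
  rate <- ifelse(mid_stable > 0, drug / mid_stable, 0)
  expect_equal(rate[month <= 12 & mid_stable > 0],
    rep(chemo_monthly + cetux_monthly, sum(month <= 12 & mid_stable > 0)),
    tolerance = 1e-9
  )
  expect_equal(rate[month > 12 & mid_stable > 0],
    rep(chemo_monthly, sum(month > 12 & mid_stable > 0)),
    tolerance = 1e-9
  )
})
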