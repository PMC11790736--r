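test_that("transition matrices are row-stochastic with the published rows", {
  p <- default_parameters()
  for (profile in c("cured", "pa", "eht")) {
    P <- transition_matrix(profile, p)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(P[4, ]), c(0, 0, 0, 1)) # death absorbing
    expect_equal(unname(P[2, c(1, 3)]), c(0, 0)) # HF exits only to death
    expect_equal(unname(P[3, c(1, 2)]), c(0, 0))
  }
  expect_equal(unname(transition_matrix("pa", p)[1, ]),
               c(1 - 0.0042 - 0.0563 - 0.129, 0.0563, 0.129, 0.0042))
  expect_equal(transition_matrix("cured", p)["htn", "stroke"], 0.0011)
  # row-stochastic under random parameter sets too
  for (seed in 1:10) {
    rp <- random_parameter_set(seed)
    for (profile in c("cured", "pa", "eht"))
      expect_equal(unname(rowSums(transition_matrix(profile, rp))), rep(1, 4),
                   tolerance = 1e-12)
  }
})

test_that("competing risks above one are rejected", {
  p <- default_parameters()
  p$pa_stroke <- 0.95 # bypasses constructor checks on purpose
  expect_error(transition_matrix("pa", p), "exceed 1")
})

test_that("a single undiscounted cycle reproduces the hand calculation", {
  p <- default_parameters(list(discount = 0))
  cfg <- model_config(half_cycle = "none", horizon_inclusive = FALSE)
  tr <- run_cohort("cured", 0, p, cycles = 1, config = cfg)
  # occupancy-weighted utility after one transition from full health
  expect_equal(tr$qaly,
               (1 - 0.00416 - 0.0266 - 0.0011) * 1.0 +
                 0.0266 * 0.9 + 0.0011 * 0.9)
})

test_that("zero-event limits have closed forms", {
  zero <- list(eht_death = 0, eht_hf = 0, eht_stroke = 0)
  # no events, no discount: QALY = cycles x u_eht
  p <- default_parameters(c(zero, discount = 0))
  cfg <- model_config(half_cycle = "none", horizon_inclusive = FALSE)
  tr <- run_cohort("eht", p$drug_eht, p, cycles = 7, config = cfg)
  expect_equal(tr$qaly, 7 * p$u_eht)
  expect_equal(tr$cost, 7 * p$drug_eht)
  # no events, discounting from the end of the first cycle: u_eht/(1+r)
  p2 <- default_parameters(zero)
  cfg2 <- model_config(half_cycle = "none", horizon_inclusive = FALSE,
                       discount_from = 1)
  tr2 <- run_cohort("eht", 0, p2, cycles = 1, config = cfg2)
  expect_equal(tr2$qaly, p2$u_eht / 1.02)
})

test_that("discounted QALY of the EHT profile is bracketed by the annuity factor", {
  p <- default_parameters()
  tr <- run_cohort("eht", p$drug_eht, p, cycles = 32)
  expect_gt(tr$qaly, 20)
  expect_lt(tr$qaly, 24)
})

test_that("trace satisfies occupancy and accumulation invariants", {
  p <- default_parameters()
  for (profile in c("cured", "pa", "eht")) {
    tr <- run_cohort(profile, 50000, p, cycles = 20, upfront_cost = 1000)$trace
    expect_equal(tr$p_htn + tr$p_hf + tr$p_stroke + tr$p_death,
                 rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$cum_cost) >= 0))
    expect_true(all(diff(tr$cum_qaly) >= 0))
    expect_equal(tr$cum_cost[nrow(tr)], 1000 + sum(tr$cost_disc))
  }
})

test_that("expected values equal the mass-weighted sum of cohort runs", {
  p <- default_parameters()
  cfg <- model_config()
  for (s in c("comprehensive", "medication_only", "cavs_rfa")) {
    sub <- resolve_strategy(s, p, cfg)
    tot <- c(cost = 0, qaly = 0)
    for (i in seq_len(nrow(sub))) {
      tr <- run_cohort(sub$risk_profile[i], sub$annual_drug_cost[i], p,
                       cycles = 32, config = cfg,
                       upfront_cost = sub$upfront_cost[i])
      tot <- tot + sub$mass[i] * c(cost = tr$cost, qaly = tr$qaly)
    }
    expect_equal(expected_values(s, p, cycles = 32, config = cfg), tot,
                 tolerance = 1e-10)
  }
})

test_that("mortality and discounting act monotonically on expected values", {
  p <- default_parameters()
  base <- expected_values("medication_only", p, sex = "male")
  for (id in c("pa_death", "eht_death", "hf_death", "stroke_death")) {
    worse <- default_parameters(stats::setNames(list(p[[id]] * 2), id))
    ev <- expected_values("medication_only", worse, sex = "male")
    expect_lte(ev[["qaly"]], base[["qaly"]])
  }
  disc <- expected_values("medication_only",
                          default_parameters(list(discount = 0.05)),
                          sex = "male")
  expect_lt(disc[["qaly"]], base[["qaly"]])
  expect_lt(disc[["cost"]], base[["cost"]])
})

test_that("entry costs add the acute-event charges when enabled", {
  p <- default_parameters()
  off <- run_cohort("eht", 0, p, cycles = 10)
  on <- run_cohort("eht", 0, p, cycles = 10,
                   config = model_config(entry_costs = TRUE))
  expect_gt(on$cost, off$cost)
  expect_equal(on$qaly, off$qaly)
})
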